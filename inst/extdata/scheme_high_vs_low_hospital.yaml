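name: high_vs_low_hospital
field: hospital_level
groups:
  high:
    - A
  low:
    - B
    - C
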