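name: acute_vs_chronic
field: disease
groups:
  acute:
    - influenza
    - infantile pneumonia
    - infantile diarrhea
    - hyperthyroidism
  chronic:
    - hypertension
    - diabetes
    - infertility
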