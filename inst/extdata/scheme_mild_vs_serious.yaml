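name: mild_vs_serious
field: disease
groups:
  mild:
    - influenza
  serious:
    - liver cancer
    - gastric cancer
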