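# Nine-topic patient-experience taxonomy for physician reviews,
# organised in three domains.
labels:
  - id: ME
    name: Medical ethics
    domain: physician-related
  - id: MC
    name: Medical competence
    domain: physician-related
  - id: MAP
    name: Medical advice and prescription
    domain: physician-related
  - id: CS
    name: Communication skills
    domain: physician-related
  - id: F
    name: Financing
    domain: system-related
  - id: OP
    name: Operation process
    domain: system-related
  - id: PP
    name: Patient profile
    domain: patient-related
  - id: S
    name: Symptoms
    domain: patient-related
  - id: DAP
    name: Diagnosis and pathogenesis
    domain: patient-related
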