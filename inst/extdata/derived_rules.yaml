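# Derived-condition rules: infer conditions never explicitly coded
# from converging evidence (minimum age + medication class + elevated
# lab result), in the spirit of inferring diabetes from metformin
# prescriptions and glycated haemoglobin. Codes refer to the default
# synthetic terminologies.
- name: derived-confounder
  min_age: 40
  medications:
    - {scheme: ATCA, code: A2_2}
  lab:
    scheme: LABA
    code: A1C
    threshold: 6.5
  condition:
    scheme: MEDC
    code: R4_2
    label: confounder analogue (derived)
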