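# Demo study definition for the shipped synthetic fixtures: verify a
# drug-reaction signal by contrasting patients with the reaction within
# 120 days after the prescription (foreground) against all users of the
# drug (background). Codes refer to the default synthetic terminologies
# (research scheme MEDC, drug scheme ATCA).
study_id: demo-signal
background:
  kind: medication
  scheme: ATCA
  codes: [A2_1]
foreground:
  op: and
  children:
    - kind: medication
      scheme: ATCA
      codes: [A2_1]
    - anchor:
        kind: medication
        scheme: ATCA
        codes: [A2_1]
      related:
        kind: condition
        scheme: MEDC
        codes: [R4_1]
      direction: after
      window_days: 120
index_anchor:
  kind: medication
  scheme: ATCA
  codes: [A2_1]
grouping:
  condition: {scheme: MEDC, level: hlgt}
  medication: {scheme: ATCA, level: class}
statistics:
  - age
  - gender
  - country
  - common_conditions
  - common_medications
  - conditions_before_index
  - conditions_after_index
  - risk_factor
risk_factors:
  - scheme: MEDC
    code: R4_2
    label: confounder analogue (diabetes-like)
reference_date: 2010-01-01
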