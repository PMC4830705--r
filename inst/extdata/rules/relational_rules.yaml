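# Conversion rules: relational CSV dialect -> common model.
# `match` names a table; bindings name its columns. Dates are ISO-8601.
- target: patient
  match: patients
  bind:
    patient_id: patient_id
    birth_year: birth_year
    gender: gender
    country: country
- target: condition
  match: conditions
  bind:
    patient_id: patient_id
    scheme: scheme
    code: code
    label: label
    start: start_date
    end: end_date
- target: medication
  match: medications
  bind:
    patient_id: patient_id
    scheme: scheme
    code: code
    label: label
    start: start_date
    end: end_date
- target: lab_result
  match: labs
  bind:
    patient_id: patient_id
    scheme: scheme
    code: code
    label: label
    start: start_date
    value_num: value
    value_unit: unit
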