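# Conversion rules: XML patient-summary dialect -> common model.
# Patterns are element paths from the document root with optional
# attribute predicates; bindings are relative paths ending in an
# attribute (`@` for the matched node itself, `^el/@a` for the nearest
# ancestor named `el`). Dates in this dialect are YYYYMMDD.
- target: patient
  match: patientSummarySet/patientSummary
  bind:
    patient_id: "@id"
    birth_year: patient/birthYear/@value
    gender: patient/gender/@code
    country: patient/country/@code
- target: condition
  match: patientSummarySet/patientSummary/section[@type=problems]/observation
  date_format: "%Y%m%d"
  bind:
    patient_id: "^patientSummary/@id"
    code: code/@code
    scheme_raw: code/@codeSystem
    label: code/@displayName
    start: effectiveTime/@value
    end: effectiveTimeEnd/@value
- target: medication
  match: patientSummarySet/patientSummary/section[@type=medications]/observation
  date_format: "%Y%m%d"
  bind:
    patient_id: "^patientSummary/@id"
    code: code/@code
    scheme_raw: code/@codeSystem
    label: code/@displayName
    start: effectiveTime/@value
    end: effectiveTimeEnd/@value
- target: lab_result
  match: patientSummarySet/patientSummary/section[@type=results]/observation
  date_format: "%Y%m%d"
  bind:
    patient_id: "^patientSummary/@id"
    code: code/@code
    scheme_raw: code/@codeSystem
    label: code/@displayName
    start: effectiveTime/@value
    value_num: value/@value
    value_unit: value/@unit
- target: procedure
  match: patientSummarySet/patientSummary/section[@type=procedures]/observation
  date_format: "%Y%m%d"
  bind:
    patient_id: "^patientSummary/@id"
    code: code/@code
    scheme_raw: code/@codeSystem
    label: code/@displayName
    start: effectiveTime/@value
- target: allergy
  match: patientSummarySet/patientSummary/section[@type=allergies]/observation
  date_format: "%Y%m%d"
  bind:
    patient_id: "^patientSummary/@id"
    code: code/@code
    scheme_raw: code/@codeSystem
    label: code/@displayName
    start: effectiveTime/@value
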