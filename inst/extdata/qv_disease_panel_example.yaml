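meta:
  qv_set_id: qv_disease_panel_v1_20250828
  version: 1.0.0
  title: Disease panel filter
  description_patient: >
    We have a strong family history of early heart attacks.
  description_ppie: >
    The PPIE group reviewed the criteria and approved them
    on 2025-08-15.
filters:
  region_include:
    description: >
      Restrict to curated disease gene panel
    logic: keep_if
    field: OVERLAP(targets.disease_panel.bed)
    operator: '> ='
    value: 1
criteria:
  pathogenic:
    description: >
      Variant classified as pathogenic or likely pathogenic
    logic: and
    conditions:
      - group: 'any_of: start'
      - {field: CLASS, operator: '==', value: P}
      - {field: CLASS, operator: '==', value: LP}
      - group: 'any_of: end'
notes:
  - Gene panel file defines the target regions.
  - Additional quality filters may be added as needed.
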