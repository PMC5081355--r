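codesets:
  mm_diagnosis:
    patterns: ICD9DX:203.0x
  chemotherapy:
    patterns:
    - CPT4:964xx
    - CPT4:965xx
    - HCPCS:J9xxx
  stem_cell_transplant:
    patterns:
    - CPT4:38240
    - CPT4:38241
  protein_electrophoresis:
    patterns:
    - CPT4:84165
    - CPT4:84166
    - CPT4:86334
    - CPT4:86335
  quantitative_immunoglobulin:
    patterns:
    - CPT4:82784
    - CPT4:82787
  serum_free_light_chain:
    patterns: CPT4:83883
  serum_albumin:
    patterns: CPT4:82040
  beta2_microglobulin:
    patterns: CPT4:82232
  bone_marrow:
    patterns:
    - CPT4:38220
    - CPT4:38221
    - CPT4:85097
  skeletal_survey:
    patterns:
    - CPT4:77074
    - CPT4:77075
  ldh:
    patterns: CPT4:83615
  corticosteroid:
    patterns: NDC:00054xxxxxx
  bisphosphonate:
    patterns:
    - NDC:00069xxxxxx
    - HCPCS:J3487
  anemia_treatment:
    patterns:
    - HCPCS:J0885
    - HCPCS:J0881
    - CPT4:36430
  monoclonal_gammopathy:
    patterns: ICD9DX:273.1
  other_malignancy:
    patterns:
    - ICD9DX:174.9
    - ICD9DX:185
    - ICD9DX:202.8x
  anemia_dx:
    patterns:
    - ICD9DX:285.x
    - ICD9DX:280.0
  osteoporosis_dx:
    patterns: ICD9DX:733.0x
  skeletal_related_event:
    patterns:
    - ICD9DX:733.1x
    - ICD9DX:198.5
  bone_pain_lesions:
    patterns:
    - ICD9DX:733.90
    - ICD9DX:719.4x
  fatigue:
    patterns: ICD9DX:780.79
  shortness_of_breath:
    patterns: ICD9DX:786.05
  chest_pain:
    patterns: ICD9DX:786.5x
  peripheral_neuropathy:
    patterns: ICD9DX:356.x
  renal_failure:
    patterns:
    - ICD9DX:584.x
    - ICD9DX:585.x
    - ICD9DX:586
  hypercalcemia:
    patterns: ICD9DX:275.42
  pneumonia:
    patterns:
    - ICD9DX:486
    - ICD9DX:481
  herpes_zoster:
    patterns: ICD9DX:053.x
  uti_kidney_infection:
    patterns:
    - ICD9DX:599.0
    - ICD9DX:590.x
groups:
  diagnostic_tests:
  - protein_electrophoresis
  - quantitative_immunoglobulin
  - serum_free_light_chain
  - serum_albumin
  - beta2_microglobulin
  - bone_marrow
  - skeletal_survey
  - ldh
  treatments:
  - corticosteroid
  - bisphosphonate
  - anemia_treatment
  symptoms:
  - monoclonal_gammopathy
  - other_malignancy
  - anemia_dx
  - osteoporosis_dx
  - skeletal_related_event
  - bone_pain_lesions
  - fatigue
  - shortness_of_breath
  - chest_pain
  - peripheral_neuropathy
  - renal_failure
  - hypercalcemia
  - pneumonia
  - herpes_zoster
  - uti_kidney_infection
options:
  wildcard_mode: zero_or_more
  dx_match: any_slot
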