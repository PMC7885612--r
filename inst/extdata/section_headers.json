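{
  "CLINICAL_HISTORY":                    ["CLINICAL HISTORY"],
  "HISTORY_OF_PRESENT_ILLNESS":          ["HISTORY OF PRESENT ILLNESS", "HPI"],
  "PAST_MEDICAL_HISTORY":                ["PAST MEDICAL HISTORY", "PMH"],
  "ALLERGIES":                           ["ALLERGIES", "ALLERGY"],
  "FAMILY_HISTORY":                      ["FAMILY HISTORY", "FHX"],
  "CHIEF_COMPLAINT":                     ["CHIEF COMPLAINT", "CC"],
  "MAJOR_SURGICAL_OR_INVASIVE_PROCEDURE": ["MAJOR SURGICAL OR INVASIVE PROCEDURE", "MAJOR SURGICAL PROCEDURE"],
  "SOCIAL_HISTORY":                      ["SOCIAL HISTORY", "SHX"],
  "SERVICE":                             ["SERVICE"]
}
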