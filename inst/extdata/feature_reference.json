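{
  "capillary_refill_rate":        {"baseline": 0.2,  "step_sd": 0.05, "normal": 0.0,  "unit": "binary"},
  "diastolic_blood_pressure":     {"baseline": 65,   "step_sd": 3.0,  "normal": 70,   "unit": "mmHg"},
  "fraction_inspired_oxygen":     {"baseline": 0.35, "step_sd": 0.02, "normal": 0.21, "unit": "fraction"},
  "gcs_eye_opening":              {"baseline": 3.5,  "step_sd": 0.3,  "normal": 4,    "unit": "score"},
  "gcs_motor_response":           {"baseline": 5.2,  "step_sd": 0.3,  "normal": 6,    "unit": "score"},
  "gcs_total":                    {"baseline": 12.5, "step_sd": 0.6,  "normal": 15,   "unit": "score"},
  "gcs_verbal_response":          {"baseline": 4.0,  "step_sd": 0.3,  "normal": 5,    "unit": "score"},
  "glucose":                      {"baseline": 130,  "step_sd": 8.0,  "normal": 110,  "unit": "mg/dL"},
  "heart_rate":                   {"baseline": 85,   "step_sd": 4.0,  "normal": 80,   "unit": "bpm"},
  "height":                       {"baseline": 168,  "step_sd": 0.0,  "normal": 168,  "unit": "cm"},
  "mean_blood_pressure":          {"baseline": 80,   "step_sd": 3.5,  "normal": 85,   "unit": "mmHg"},
  "oxygen_saturation":            {"baseline": 96,   "step_sd": 1.2,  "normal": 98,   "unit": "%"},
  "respiratory_rate":             {"baseline": 18,   "step_sd": 1.5,  "normal": 16,   "unit": "breaths/min"},
  "systolic_blood_pressure":      {"baseline": 120,  "step_sd": 5.0,  "normal": 118,  "unit": "mmHg"},
  "temperature":                  {"baseline": 37.0, "step_sd": 0.25, "normal": 36.8, "unit": "C"},
  "weight":                       {"baseline": 78,   "step_sd": 0.0,  "normal": 78,   "unit": "kg"},
  "ph":                           {"baseline": 7.38, "step_sd": 0.02, "normal": 7.40, "unit": "pH"}
}
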