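{
  "gcs_eye_opening": {
    "none": 1, "to pain": 2, "to speech": 3, "spontaneously": 4
  },
  "gcs_verbal_response": {
    "no response": 1, "no response-ett": 1, "incomprehensible sounds": 2,
    "inappropriate words": 3, "confused": 4, "oriented": 5
  },
  "gcs_motor_response": {
    "no response": 1, "abnormal extension": 2, "abnormal flexion": 3,
    "flex-withdraws": 4, "localizes pain": 5, "obeys commands": 6
  }
}
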