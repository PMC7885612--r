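# Synthetic chronic-condition ICD-9 code list (one undotted code per line).
# Covers common chronic diagnoses (hypertension, diabetes, CHF, COPD, CKD,
# cirrhosis, CAD, atrial fibrillation, asthma, immune suppression); assembled
# for testing, not copied from any licensed grouping.
4019
40190
4011
25000
25002
25040
4280
42822
42832
496
49120
49320
5859
58581
5856
571
5712
5715
41401
4140
42731
2720
2724
2449
V5867
042
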