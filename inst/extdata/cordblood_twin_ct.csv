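assay,FRAT_A,FRAT_B,IDENT_A,IDENT_B
miR-181d,22.93,15.92,21.18,21.60
miR-29a,22.93,17.12,21.18,21.95
miR-34b,23.88,17.89,Undetermined,Undetermined
miR-125d,22.93,17.94,23.18,Undetermined
miR-20a,22.23,17.95,21.18,21.66
miR-10a,21.93,18.97,23.18,21.71
miR-19a,Undetermined,Undetermined,26.18,22.20
miR-107,21.93,Undetermined,23.18,Undetermined
miR-10b,Undetermined,Undetermined,Undetermined,Undetermined
U6-2,32.00,32.00,32.00,32.00
SNORD48,32.00,32.00,32.00,32.00
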