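mirna,zygosity,fold
miR-129-3p,fraternal,8248.98
miR-106b,fraternal,7858.29
miR-34c-3p,fraternal,2105.57
miR-34a,fraternal,261.37
miR-125a-3p,fraternal,131.59
miR-181d,fraternal,128.89
miR-17,fraternal,123.63
miR-519d,fraternal,66.25
miR-34b,fraternal,63.55
miR-181b,fraternal,61.81
miR-181a,fraternal,56.10
miR-29a,fraternal,56.10
miR-125b,fraternal,31.77
miR-181c,fraternal,31.12
miR-19a,fraternal,30.69
miR-144,fraternal,28.24
miR-20a,fraternal,19.42
miR-520h,fraternal,17.38
miR-130a,fraternal,15.45
miR-34c-5p,fraternal,13.64
miR-223,fraternal,1.97
miR-155,fraternal,1.94
miR-107,fraternal,1.93
miR-142-5p,fraternal,1.91
miR-411,fraternal,1.35
miR-221,fraternal,1.00
miR-92a,fraternal,1.00
miR-10b,fraternal,1.00
miR-20b,fraternal,1.00
miR-93,fraternal,1.00
miR-181b,identical,837.53
miR-181c,identical,689.78
miR-144,identical,352.13
miR-130a,identical,158.68
miR-125a-3p,identical,93.05
miR-519d,identical,47.17
miR-520h,identical,47.17
miR-181a,identical,24.08
miR-19b,identical,23.75
miR-17,identical,22.16
miR-19a,identical,15.77
miR-92a,identical,10.92
miR-24,identical,10.63
miR-29a,identical,1.70
miR-221,identical,1.47
miR-20a,identical,1.39
miR-155,identical,1.38
miR-22,identical,1.38
miR-411,identical,1.37
miR-181d,identical,1.33
miR-16,identical,1.31
miR-34c-3p,identical,1.31
miR-106b,identical,1.21
miR-34a,identical,1.20
miR-34b,identical,1.20
miR-34c-5p,identical,1.16
miR-9,identical,1.01
miR-129-3p,identical,1.00
miR-125b,identical,1.00
miR-10b,identical,1.00
miR-125a-5p,identical,1.00
miR-128,identical,1.00
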