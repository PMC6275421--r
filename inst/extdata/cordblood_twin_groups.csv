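mirna,group
miR-129-3p,A
miR-106b,A
miR-34c-3p,A
miR-34a,A
miR-34b,A
miR-29a,A
miR-125b,A
miR-34c-5p,A
miR-20a,A
miR-181b,B
miR-181c,B
miR-144,B
miR-520h,B
miR-130a,B
miR-181d,C
miR-17,C
miR-519d,C
miR-181a,C
miR-19a,C
miR-125a-3p,C
miR-24,D
miR-19b,D
miR-92a,D
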