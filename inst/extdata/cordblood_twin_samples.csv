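sample_id,pair_id,member,zygosity
FRAT_A,FR1,A,fraternal
FRAT_B,FR1,B,fraternal
IDENT_A,ID1,A,identical
IDENT_B,ID1,B,identical
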