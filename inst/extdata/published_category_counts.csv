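score,n_high,n_low,bleeds_high,bleeds_low
HASBLED,609,752,163,87
ATRIA,302,1059,74,176
ORBIT,319,1042,85,165
HEMORR2HAGES,1018,343,206,44
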