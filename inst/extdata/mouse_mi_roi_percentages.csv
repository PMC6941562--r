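section_index,manual_collagen_pct,manual_fibrosis_pct,auto_collagen_pct,auto_fibrosis_pct
1,NA,NA,NA,NA
2,16.3,17.9,17.11,6.15
3,10.7,9.6,4.07,5.33
4,10.6,7.4,1.11,3.83
5,11.5,6.6,2.17,4.62
6,8,0,0.13,3.55
7,NA,0,NA,3.19
8,NA,0,NA,4.35
9,NA,0,NA,3.48
10,NA,0,NA,4.12
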