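section_index,manual_total_px,manual_infarct_px,auto_total_px,auto_infarct_px
1,NA,NA,NA,NA
2,79048,43023,65841,21610
3,149106,45402,103116,18666
4,214502,43172,174738,16941
5,338169,61102,275569,27678
6,433953,29029,338801,17933
7,462939,0,353645,11271
8,479865,0,372602,16221
9,470169,0,381734,13290
10,476956,0,369464,15220
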