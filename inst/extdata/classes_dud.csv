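no,subset,n_decoys,n_actives
1,FGFR1T,4550,120
2,FXA,5745,146
3,GART,879,40
4,GBP,2140,52
5,GR,2947,78
6,HIVPR,2038,62
7,HIVRT,1519,43
8,HMGA,1480,35
9,HSP90,979,37
10,MR,636,15
11,NA,1874,49
12,PR,1041,27
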