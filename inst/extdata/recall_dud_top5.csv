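class_label,TAN,SQB,MLP
FGFR1T,6.67,7,8.17
FXA,7.88,8.29,7.95
GART,22.25,23.25,25.00
GBP,20.96,30.96,10.00
GR,6.41,8.46,7.69
HIVPR,11.77,11.29,13.87
HIVRT,4.88,6.98,9.09
HMGA,10.29,13.14,21.11
HSP90,8.11,8.38,13.68
MR,9.33,10,16.25
NA,5.1,9.8,10.00
PR,4.81,5.19,7.14
__mean__,9.87,11.90,12.50
__shaded__,0,3,9
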