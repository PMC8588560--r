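class_label,TAN,SQB,MLP
FGFR1T,2.5,2.92,3.17
FXA,1.92,3.36,1.64
GART,7.75,5.75,8.00
GBP,13.27,15.96,3.46
GR,2.31,3.21,3.08
HIVPR,3.55,3.55,5.16
HIVRT,1.63,1.86,5.00
HMGA,6.29,5.43,11.67
HSP90,1.62,4.05,4.21
MR,5.33,5.33,10.00
NA,2.24,5.31,5.20
PR,1.85,2.22,4.29
__mean__,4.19,4.91,5.41
__shaded__,0,4,8
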