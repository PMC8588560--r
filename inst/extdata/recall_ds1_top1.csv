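class_label,TAN,BIN,SQB,SDBN,MLP
31420,69.69,74.08,73.73,74.21,82.1416
71523,25.94,28.26,26.84,27.97,49.4118
37110,9.63,26.05,24.73,26.03,45.5639
31432,35.82,39.23,36.66,39.79,45.5957
42731,17.77,21.68,21.17,23.06,32.0546
6233,13.87,14.06,12.49,19.29,22.9708
6245,6.51,6.31,6.03,6.27,5.36313
7701,8.63,11.45,11.35,14.05,12.0918
6235,9.71,10.84,10.15,12.87,10.7767
78374,13.69,14.25,13.08,17.47,21.9196
78331,7.17,6.03,5.92,9.93,9.70199
__mean__,19.86,22.93,22.01,24.63091,30.69
__shaded__,1,0,0,3,7
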