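class_label,TAN,BIN,SQB,SDBN,MLP
9249,24.17,25.72,17.8,31.61,61.1556
12455,10.29,14.65,11.42,16.29,27.1429
12464,15.22,16.55,16.79,20.9,53.72
31281,29.62,28.29,29.05,36.13,75.8
43210,16.07,14.41,14.12,22.09,36.2105
71522,12.37,8.44,13.82,14.68,15.9143
75721,25.21,30.02,30.61,41.07,78.2333
78331,15.01,12.03,11.97,17.13,78.2
78348,24.67,20.76,21.14,26.93,25.4667
78351,11.71,12.94,13.3,17.87,34.2667
__mean__,18.43,18.38,18.00,24.47,48.611
__shaded__,0,0,0,1,9
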