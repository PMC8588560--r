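class_label,TAN,BIN,SQB,SDBN,MLP
9249,12.12,15.33,10.99,19.47,39.7556
12455,6.57,9.37,7.03,13.29,9.8
12464,8.17,8.45,6.92,12.91,31.84
31281,16.95,18.29,18.67,23.62,61.8
43210,6.27,7.34,6.83,14.23,17.5789
71522,3.75,4.08,6.57,11.92,6.42857
75721,17.32,20.41,20.38,29.08,57.5667
78331,6.31,7.51,6.16,11.93,41.3
78348,10.15,9.79,8.99,9.17,12.2
78351,9.84,13.68,12.5,18.13,14.3024
__mean__,9.75,11.43,10.50,16.375,29.257217
__shaded__,0,0,0,3,7
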