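class_label,TAN,BIN,SQB,SDBN,MLP
31420,83.49,87.61,87.22,89.03,87.3628
71523,48.92,52.72,48.70,65.17,75.8289
37110,21.01,48.20,45.62,41.25,71.4536
31432,74.29,77.57,70.44,79.87,84.1489
42731,29.68,26.63,24.35,31.92,51.3644
6233,27.68,23.49,20.04,29.31,49.443
6245,16.54,14.86,13.72,21.06,16.0894
7701,24.09,27.79,26.73,28.43,29.7449
6235,20.06,23.78,22.81,27.82,28.7379
78374,20.51,20.20,19.56,19.09,36.7857
78331,16.20,11.80,11.37,16.21,24.1391
__mean__,34.77,37.70,35.51,40.83273,50.463
__shaded__,0,0,0,2,9
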