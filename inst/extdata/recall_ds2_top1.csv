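class_label,TAN,BIN,SQB,SDBN,MLP
7707,61.84,72.18,72.09,83.19,86.4706
7708,47.03,96.00,95.68,94.82,97.3077
31420,65.10,79.82,78.56,79.27,71.7699
42710,81.27,76.27,76.82,74.81,82.9091
64100,80.31,88.43,87.80,93.65,94.2769
64200,53.84,70.18,70.18,71.16,35.5696
64220,38.64,68.32,67.58,68.71,88.5333
64500,30.56,81.20,79.20,75.62,62.8571
64350,80.18,81.89,81.68,85.21,91.8557
75755,87.56,98.06,98.02,96.52,90.5727
__mean__,62.63,81.24,80.76,82.296,80.21226
__shaded__,0,3,0,1,6
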