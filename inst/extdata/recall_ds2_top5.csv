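class_label,TAN,BIN,SQB,SDBN,MLP
7707,70.39,74.81,74.37,73.9,94.2157
7708,56.58,99.61,99.61,98.22,98.7179
31420,88.19,95.46,94.88,95.64,92.9381
42710,88.09,92.55,91.09,90.12,88
64100,93.75,99.22,99.03,99.05,96.6615
64200,77.68,99.2,99.38,93.76,38.6076
64220,52.19,91.32,90.62,96.01,93.2381
64500,44.8,94.96,92.48,91.51,71.2698
64350,91.71,91.47,90.78,86.94,95.3608
75755,94.82,98.35,98.37,91.6,93.8767
__mean__,75.82,93.70,93.06,91.675,86.28862
__shaded__,0,4,3,2,2
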