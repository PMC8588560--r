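class_label,TAN,BIN,SQB,MLP
466,5.86,10.44,8.62,12
548,22.76,27.22,24.14,46.6667
600,11.38,12.89,16.21,20.6667
644,17.59,19.67,17.93,25.3333
652,7.93,11.67,9.66,17.3333
689,9.66,13.22,11.72,15.3333
692,4.83,9.22,4.83,14.6667
712,10.34,16.45,11.03,14
713,7.24,9,5.86,12
733,8.97,10.11,8.62,9.33333
737,8.28,12,8.28,12
810,6.9,13.33,11.03,10
832,13.1,20.44,14.83,24.6667
846,28.62,26.11,26.9,36.6667
852,21.38,23.11,20,34.6667
858,5.86,9.11,6.21,14
859,8.97,9.44,8.62,11.3333
__mean__,11.74529412,14.90765,12.61706,19.45098412
__shaded__,0,4,0,13
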