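class_label,TAN,BIN,SQB,MLP
466,3.1,6.33,1.38,6.66667
548,8.62,14.89,11.38,28.6667
600,3.79,6.33,5.52,14.6667
644,7.59,11,8.97,14.6667
652,2.76,7,3.79,12
689,3.79,7.33,4.48,8
692,0.69,5.33,1.38,6.66667
712,4.14,8.22,5.17,8.66667
713,3.1,5.89,2.76,6
733,3.45,6.67,4.14,6
737,2.41,5.11,1.72,7.33333
810,2.07,6.78,1.72,6.66667
832,6.55,12.55,8.28,16.6667
846,9.66,13.11,12.41,16
852,12.41,13.78,9.66,18
858,1.72,5.11,1.38,7.33333
859,1.38,4.89,2.41,6.66667
__mean__,4.542941,8.254118,5.091176,11.21569471
__shaded__,0,2,0,12
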