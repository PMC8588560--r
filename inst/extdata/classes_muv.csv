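"activity_index","n_actives","class_name","target_diversity"
"66","30","S1P1 rec. (agonists)","0.117"
"644","30","Rho-Kinase2 (inhibitors)","0.122"
"600","30","SF1 (inhibitors)","0.123"
"689","30","Eph rec. A4 (inhibitors)","0.113"
"652","30","HIV RT-RNase (inhibitors)","0.099"
"712","30","HSP 90 (inhibitors) 30","0.106"
"692","30","SF1 (agonists)","0.114"
"733","30","ER-b-Coact. Bind. (inhibitors)","0.114"
"713","30","ER-a-Coact. Bind. (inhibitors)","0.113"
"810","30","FAK (inhibitors)","0.107"
"737","30","ER-a-Coact. Bind. (potentiators)","0.129"
"846","30","FXIa (inhibitors)","0.161"
"832","30","Cathepsin G (inhibitors)","0.151"
"858","30","D1 rec. (allosteric modulators)","0.111"
"852","30","FXIIa (inhibitors)","0.150"
"548","30","PKA (inhibitors)","0.128"
"859","30","M1 rec. (allosteric inhibitors)","0.126"
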