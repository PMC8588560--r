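"activity_index","n_actives","class_name","target_diversity"
"09249","900","Muscarinic (M1) agonists","0.111"
"31281","106","Dopamine -hydroxylase inhibitors","0.125"
"12464","505","Nitric oxide synthase inhibitors","0.102"
"71522","700","Reverse transcriptase inhibitors","0.103"
"43210","957","Aldose reductase inhibitors","0.119"
"12455","1400","NMDA receptor antagonists","0.098"
"75721","636","Aromatase inhibitors","0.110"
"78351","2111","Lipoxygenase inhibitors","0.113"
"78348","617","Phospholipase A2 inhibitors","0.123"
"78331","636","Cyclooxygenase inhibitors","0.108"
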