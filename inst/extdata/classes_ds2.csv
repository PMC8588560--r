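"activity_index","n_actives","class_name","target_diversity"
"07707","207","Adenosine (A1) agonists","0.229"
"42710","111","CCK agonists","0.361"
"31420","1130","Renin inhibitors","0.290"
"64200","113","Cephalosporins","0.322"
"64100","1346","Monocyclic lactams","0.336"
"64500","126","Carbapenems","0.260"
"64220","1051","Carbacephems","0.269"
"75755","455","Vitamin D analogous","0.386"
"75755","455","Vitamin D analogous","0.386"
"07708","156","Adenosine (A2) agonists","0.305"
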