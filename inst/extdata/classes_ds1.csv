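"activity_index","n_actives","class_name","target_diversity"
"31420","1130","Renin inhibitors","0.290"
"31432","943","Angiotensin II AT1 antagonists","0.229"
"37110","803","Thrombin inhibitors","0.180"
"71523","750","HIV protease inhibitors","0.198"
"42731","1246","Substance P antagonists","0.149"
"07701","395","D2 antagonists","0.138"
"06245","359","5HT reuptake inhibitors","0.122"
"78374","453","Protein kinase C inhibitors","0.120"
"06235","827","5HT1A agonists","0.133"
"06233","752","5HT3 antagonist","0.140"
"78331","636","Cyclooxygenase inhibitors","0.108"
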