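level,system,tp,tn,fp,fn,reported_precision,reported_recall,reported_f1
snippet,RISS,204,832,2,3,0.99,0.99,0.99
snippet,ISS,380,642,10,9,0.97,0.98,0.98
snippet,DS,165,852,13,11,0.93,0.94,0.93
snippet,UNCLEAR,313,693,6,29,0.98,0.92,0.95
patient,RISS,11,88,1,0,0.92,1.00,0.96
patient,ISS,25,73,1,1,0.96,0.96,0.96
patient,DS,19,78,2,1,0.90,0.95,0.92
patient,UNCLEAR,18,78,3,1,0.86,0.95,0.90
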