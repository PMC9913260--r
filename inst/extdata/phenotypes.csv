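breed,breed_name,bw1,bw14,bw28,nod,nod_category,nitrate,nitrate_category,no_oxidation,no_oxidation_category,breed_type,meat_category
BR,Broiler,47.5,305,1157,3.3,low,145.4,high,98.1,high,meat,meat
WC,White Cornish,49.3,291.7,1287.5,9.5,low,152.2,high,96.9,high,meat,meat
PRW,Plymouth Rock White,44.9,265.2,1058.4,141.8,high,0,low,2.6,low,dual_purpose,meat
YC,Yurlov Crower,39,101.3,240,149.6,high,0,low,2,low,dual_purpose,no
BB,Brahma Buff,38.2,107.5,241.7,36,low,100,high,74.1,high,dual_purpose,no
OMF,Orloff Mille Fleur,35.5,93.1,167.8,131.5,high,0,low,2.1,low,dual_purpose,no
LR,Layer,42.4,79.8,222.4,138.9,high,0,low,2.4,low,egg,no
UG,Uzbek Game,41.3,92.4,223.7,8.8,low,143.4,high,96.9,high,game,no
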