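breed,tissue,lo,hi
BR,breast,1,6
BR,thigh,1,4
WC,breast,1,6
WC,thigh,3,7
PRW,breast,1,4
PRW,thigh,1,4
YC,breast,1,6
YC,thigh,1,4
BB,breast,2,7
BB,thigh,1,4
OMF,breast,2,6
OMF,thigh,1,4
LR,breast,1,6
LR,thigh,1,4
UG,breast,1,6
UG,thigh,1,4
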