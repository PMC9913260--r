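breed,tissue,mode
BR,breast,free
BR,thigh,free
WC,breast,free
WC,thigh,zero
PRW,breast,zero
PRW,thigh,zero
YC,breast,zero
YC,thigh,zero
BB,breast,zero
BB,thigh,zero
OMF,breast,zero
OMF,thigh,zero
LR,breast,zero
LR,thigh,zero
UG,breast,zero
UG,thigh,free
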