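breed,tissue,gene,fc
BR,breast,MSTN,11.55
BR,breast,GHR,6.63
BR,breast,MEF2C,6.59
BR,breast,MYOD1,11.31
BR,breast,MYOG,7.46
BR,breast,MYH1,-41760
BR,breast,MYF5,-7.57
BR,thigh,MSTN,3.86
BR,thigh,GHR,3.07
BR,thigh,MEF2C,2.36
BR,thigh,MYOD1,18.77
BR,thigh,MYOG,6.73
BR,thigh,MYH1,-10020
BR,thigh,MYF5,-6.45
WC,breast,MSTN,4.89
WC,breast,GHR,5.62
WC,breast,MEF2C,2.91
WC,breast,MYOD1,2.19
WC,breast,MYOG,-4.32
WC,breast,MYH1,-16.22
WC,breast,MYF5,-685.02
WC,thigh,MSTN,4.03
WC,thigh,GHR,3.05
WC,thigh,MEF2C,-1.69
WC,thigh,MYOD1,-12.13
WC,thigh,MYOG,-4640.29
WC,thigh,MYH1,-335.46
WC,thigh,MYF5,-25531.63
PRW,breast,MSTN,6.59
PRW,breast,GHR,4.35
PRW,breast,MEF2C,4
PRW,breast,MYOD1,2.87
PRW,breast,MYOG,78.25
PRW,breast,MYH1,-24.42
PRW,breast,MYF5,-4.76
PRW,thigh,MSTN,4.5
PRW,thigh,GHR,2.95
PRW,thigh,MEF2C,-1.02
PRW,thigh,MYOD1,13.18
PRW,thigh,MYOG,1.39
PRW,thigh,MYH1,-115.36
PRW,thigh,MYF5,-33.36
YC,breast,MSTN,121.9
YC,breast,GHR,69.1
YC,breast,MEF2C,302.3
YC,breast,MYOD1,-7.11
YC,breast,MYOG,2.04
YC,breast,MYH1,1.07
YC,breast,MYF5,-5.9
YC,thigh,MSTN,46.53
YC,thigh,GHR,26.1
YC,thigh,MEF2C,494.56
YC,thigh,MYOD1,28.44
YC,thigh,MYOG,1.39
YC,thigh,MYH1,2.3
YC,thigh,MYF5,195.36
BB,breast,MSTN,41.07
BB,breast,GHR,31.78
BB,breast,MEF2C,219.8
BB,breast,MYOD1,-25.46
BB,breast,MYOG,-1.95
BB,breast,MYH1,-1.73
BB,breast,MYF5,-8.57
BB,thigh,MSTN,8.86
BB,thigh,GHR,3.72
BB,thigh,MEF2C,63.39
BB,thigh,MYOD1,8.78
BB,thigh,MYOG,-2.7
BB,thigh,MYH1,1.37
BB,thigh,MYF5,38.02
OMF,breast,MSTN,2.41
OMF,breast,GHR,3.32
OMF,breast,MEF2C,2.33
OMF,breast,MYOD1,16.11
OMF,breast,MYOG,5.58
OMF,breast,MYH1,-16270
OMF,breast,MYF5,-37.53
OMF,thigh,MSTN,-1.28
OMF,thigh,GHR,1.62
OMF,thigh,MEF2C,1.78
OMF,thigh,MYOD1,6.06
OMF,thigh,MYOG,3.63
OMF,thigh,MYH1,-8481
OMF,thigh,MYF5,-18.9
LR,breast,MSTN,4.72
LR,breast,GHR,4.79
LR,breast,MEF2C,4.14
LR,breast,MYOD1,4.59
LR,breast,MYOG,1.03
LR,breast,MYH1,-29.45
LR,breast,MYF5,-66.26
LR,thigh,MSTN,1.25
LR,thigh,GHR,1.31
LR,thigh,MEF2C,2.46
LR,thigh,MYOD1,1.08
LR,thigh,MYOG,-78.25
LR,thigh,MYH1,6.23
LR,thigh,MYF5,-87.43
UG,breast,MSTN,1.18
UG,breast,GHR,2.51
UG,breast,MEF2C,1.45
UG,breast,MYOD1,-81.01
UG,breast,MYOG,-106.9
UG,breast,MYH1,-11990
UG,breast,MYF5,-4.47
UG,thigh,MSTN,3.25
UG,thigh,GHR,4.92
UG,thigh,MEF2C,-4.79
UG,thigh,MYOD1,-13.93
UG,thigh,MYOG,-118.6
UG,thigh,MYH1,-17560
UG,thigh,MYF5,-2.43
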