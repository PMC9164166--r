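treatment,z_top_cm,z_bot_cm,theta_fc,theta_red,theta_pwp,theta_s,bd,clay,sand,silt,soc
DL,0,15,0.33,0.23,0.13,0.51,1.2,16.8,8.3,74.9,1.06
DL,15,30,0.31,0.22,0.13,0.47,1.32,16.8,8.3,74.9,0.94
DL,30,45,0.32,0.24,0.15,0.47,1.33,20.4,6.5,73.1,0.63
DL,45,50,0.32,0.25,0.17,0.43,1.47,24.9,7.3,67.8,0.41
DL,50,60,0.32,0.26,0.19,0.39,1.59,26.9,6.7,66.4,0.4
DL,60,70,0.32,0.26,0.2,0.4,1.58,28.1,6.2,65.7,0.38
DL,70,78,0.33,0.27,0.2,0.41,1.55,29.2,6.7,64.1,0.41
DL,78,210,0.32,0.26,0.19,0.4,1.58,27.3,7.9,64.8,0.33
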