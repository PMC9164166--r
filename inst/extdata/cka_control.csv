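treatment,z_top_cm,z_bot_cm,theta_fc,theta_red,theta_pwp,theta_s,bd,clay,sand,silt,soc
control,0,15,0.31,0.22,0.13,0.48,1.3,16.8,8.3,74.9,0.78
control,15,30,0.3,0.22,0.13,0.42,1.5,16.8,8.3,74.9,0.88
control,30,45,0.31,0.23,0.16,0.4,1.56,20.4,6.5,73.1,0.59
control,45,50,0.32,0.25,0.18,0.42,1.5,24.9,7.3,67.8,0.43
control,50,60,0.32,0.26,0.19,0.41,1.53,26.9,6.7,66.4,0.4
control,60,70,0.32,0.26,0.2,0.4,1.57,28.1,6.2,65.7,0.37
control,70,78,0.32,0.26,0.2,0.4,1.59,29.2,6.7,64.1,0.31
control,78,210,0.32,0.25,0.19,0.39,1.61,27.3,7.9,64.8,0.26
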