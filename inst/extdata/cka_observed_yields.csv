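season,treatment,crop,grain_obs,grain_obs_sd,grain_sim_3d,grain_sim_1d,agb_obs,agb_obs_sd,agb_sim_3d,agb_sim_1d
2017,DL,spring_barley,3.9,1.3,4.8,4.8,7.6,1.5,11.6,11.8
2017,control,spring_barley,4.5,0.9,4.6,4.8,8.1,1.7,11.0,11.8
2018,DL,spring_barley,5.6,1.0,5.5,6.2,10.1,2.0,10.7,12.2
2018,control,spring_barley,4.6,1.4,4.0,6.1,8.9,2.1,7.3,12.1
2017/18,DL,winter_wheat,2.3,0.6,4.0,4.1,4.8,1.2,7.7,7.9
2017/18,control,winter_wheat,2.7,0.3,4.0,4.1,6.0,0.7,7.7,7.9
2018/19,DL,winter_wheat,7.5,0.4,7.7,7.7,14.4,0.9,14.8,14.9
2018/19,control,winter_wheat,8.0,0.2,7.7,7.7,14.3,0.3,14.8,14.9
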