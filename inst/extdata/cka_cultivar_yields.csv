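season,treatment,crop,cultivar,grain_obs,grain_obs_sd,agb_obs,agb_obs_sd
2019,DL,spring_barley,Sydney,5.1,0.4,9.6,0.4
2019,DL,spring_barley,Eunova,4.5,0.4,8.4,0.6
2019,DL,spring_barley,Salome,4.8,0.9,9.0,0.7
2019,control,spring_barley,Sydney,5.1,1.1,9.6,1.1
2019,control,spring_barley,Eunova,4.9,0.7,9.7,0.7
2019,control,spring_barley,Salome,4.7,0.9,8.8,0.9
2019/20,DL,winter_wheat,Milaneco,6.8,0.9,16.0,0.7
2019/20,DL,winter_wheat,Trebelir,5.7,0.9,14.6,1.3
2019/20,DL,winter_wheat,Capo,6.9,0.5,15.3,1.0
2019/20,control,winter_wheat,Milaneco,7.0,0.5,15.1,1.0
2019/20,control,winter_wheat,Trebelir,5.9,0.4,14.6,2.4
2019/20,control,winter_wheat,Capo,5.9,0.4,12.0,1.1
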