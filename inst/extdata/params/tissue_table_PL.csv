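class_id,class,chi_mean_ppm,a_ppm,b_ppm,c_ppm,r2_mean_hz,a_r2_hz,modify_r2,smooth_excluded,background_source,stats_excluded
0,external_air,9.2,0,0,0,NA,NA,0,1,1,1
1,aorta,0.088,0.151,-0.412,0.292,NA,NA,0,0,0,0
2,inferior_vena_cava,0.295,-0.271,0.231,1.176,NA,NA,0,0,0,0
3,right_kidney,0.255,0.091,-1.437,0.111,NA,NA,0,0,0,0
4,left_kidney,0.257,0.472,-0.874,0.271,NA,NA,0,0,0,0
5,liver,0.182,-0.111,0.573,0.854,NA,NA,0,0,0,0
6,spleen,0.181,0.091,0.030,0.653,NA,NA,0,0,0,0
7,gallbladder,0.204,-0.030,-0.030,1.156,NA,NA,0,0,0,0
8,esophagus,0.125,0.171,-0.653,0.271,NA,NA,0,0,0,0
9,stomach,0.126,-0.050,-0.050,0.452,NA,NA,0,0,0,0
10,pancreas,0.096,0.352,-1.015,-0.010,NA,NA,0,0,0,0
11,small_intestine,0.159,0.111,-0.513,0.312,NA,NA,0,0,0,0
12,large_intestine,4.84,0,0,0,NA,NA,0,1,1,1
13,hepatic_veins,0.309,-0.472,0.332,-0.794,NA,NA,0,1,0,0
14,portal_vein,0.266,-0.131,0.814,1.096,NA,NA,0,1,0,0
15,ribs,-0.109,0.030,0.412,0.975,NA,NA,0,0,0,0
16,vertebrae,-0.004,-0.111,0.251,1.055,NA,NA,0,0,0,0
17,intervertebral_disks,0.050,-0.050,0.312,0.633,NA,NA,0,0,0,0
18,spinal_cord,0.088,-0.010,-0.352,0.714,NA,NA,0,0,0,0
19,subcutaneous_fat,0.215,-0.372,-0.111,0.171,NA,NA,0,0,0,0
20,visceral_fat,0.344,-0.251,-0.714,0.452,NA,NA,0,0,0,0
21,heart,0,0,0,0,NA,NA,0,1,0,0
22,muscle,0,0.292,-1.156,0.533,NA,NA,0,0,0,0
23,internal_air,4.84,0,0,0,NA,NA,0,1,1,1
24,liver_lobe,0.200,-0.111,0.573,0.854,150,60,1,0,0,0
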