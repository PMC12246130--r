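id,gender,age_yrs,disease_duration_yrs,years_since_initial_surgery,subtype,ledd_mg,ecg_artifact,days_after_implantation,amp_v1_l,amp_v1_r,freq_v1_l,freq_v1_r,pw_v1_l,pw_v1_r,beta_peak_v1_l,beta_peak_v1_r,days_after_visit1,amp_v2_l,amp_v2_r,freq_v2_l,freq_v2_r,pw_v2_l,pw_v2_r,beta_peak_v2_l,beta_peak_v2_r
1,M,73,20,8,T,499,Y,99,2.1,2.7,180,180,90,140,15.1,15.7,28,2.1,2.6,180,180,90,140,15.0,15.3
2,F,56,25,8,AR,560,Y,0,1.6,1.5,80,80,60,60,22.0,31.9,325,1.3,1.4,130,130,60,60,22.2,30.9
3,M,71,34,6,T,300,Y,50,2.2,2.6,125,125,60,60,21.7,14.3,94,2.1,2.5,125,125,60,60,20.7,14.4
4,F,52,18,6,AR,560,N,0,2.3,3.5,125,125,60,60,18.8,21.6,94,2.3,3.5,130,130,60,60,18.6,19.5
5,M,64,31,9,T,700,Y,50,2.9,4.0,130,130,60,60,30.7,23.3,120,2.9,4.0,130,130,60,60,32.4,25.0
6,M,69,13,7,T,450,Y,29,2.8,4.0,180,180,60,60,22.4,19.4,199,2.6,4.0,180,180,60,60,20.0,17.4
7,F,61,19,11,AR,1810,Y,24,4.2,2.2,130,130,60,60,23.2,17.8,118,4.2,2.1,130,130,60,60,23.4,20.2
8,M,68,10,5,AR,200,Y,67,1.9,4.4,130,130,60,60,30.5,26.1,118,2.2,4.6,130,130,60,60,30.3,23.7
9,M,76,16,7,AR,580,Y,87,2.8,2.8,130,130,60,60,24.3,21.5,224,2.8,2.8,130,130,60,60,22.3,23.4
10,F,58,16,11,T,400,Y,78,2.6,3.0,130,130,60,60,14.8,17.6,107,2.6,2.9,130,130,60,60,15.5,18.7
11,M,84,17,6,AR,100,Y,176,2.8,2.5,130,130,60,60,20.2,22.0,108,2.8,2.8,130,130,60,60,21.6,21.5
12,M,72,16,4,AR,1800,Y,46,3.5,3.7,130,130,60,60,26.2,19.1,104,3.6,3.8,130,130,60,60,25.3,19.1
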