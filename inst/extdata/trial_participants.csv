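subject,age_years,sex,education_years,prevailing_band,site,stim_frequency_hz
1,51,F,16,theta,F3,30
2,49,F,12,theta,C3,30
3,51,F,13,theta,CP5,30
4,56,F,13,alpha1,C4/CP2,30
5,55,F,16,theta,C3/CP5,30
6,49,F,9,theta,Cz-Fz,30
7,55,F,8,theta,CP5,30
8,50,M,11,alpha2,Cz-Pz,4
9,50,F,13,alpha2,Pz,4
10,50,F,16,theta,F4,30
11,65,F,9,delta,C3,30
12,53,F,11,theta,CP5,30
13,57,F,13,theta,CP5,30
14,52,F,8,beta,C3,4
15,53,M,17,beta,Pz,4
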