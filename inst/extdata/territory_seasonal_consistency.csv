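territory,time_between_seasons,chi2,df,p
T1,1,31.56,4,NA
T1,2,15.15,4,NA
T1,3,NA,1,0.056
T2,1,8.76,4,NA
T2,2,8.91,4,NA
T2,3,NA,1,0.287
T3,1,17.13,4,NA
T3,2,11.00,4,NA
T3,3,NA,1,0.220
T4,1,8.17,4,NA
T4,2,6.07,4,NA
T4,3,NA,1,0.211
T5,1,15.60,4,NA
T5,2,5.17,4,NA
T5,3,NA,1,0.127
T6,1,17.24,4,NA
T6,2,10.16,4,NA
T6,3,NA,1,0.502
T7,1,4.73,4,NA
T7,2,8.65,4,NA
T7,3,NA,1,0.500
All,1,103.19,28,NA
All,2,65.12,28,NA
All,3,21.30,14,0.094
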