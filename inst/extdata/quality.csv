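sample_id,variable,mean,sd,n
100S/0F,AV,0.18,0,3
90S/10F,AV,0.34,0,3
80S/20F,AV,0.39,0.01,3
70S/30F,AV,0.49,0.03,3
60S/40F,AV,0.52,0.01,3
50S/50F,AV,0.67,0.03,3
40S/60F,AV,0.69,0.04,3
30S/70F,AV,0.62,0.01,3
20S/80F,AV,0.69,0.03,3
10S/90F,AV,0.84,0.06,3
0S/100F,AV,1.26,0.06,3
Control,AV,0.32,0.01,3
100S/0F,PV,1.6,0.01,3
90S/10F,PV,1.51,0.05,3
80S/20F,PV,1.46,0,3
70S/30F,PV,1.19,0.02,3
60S/40F,PV,1.2,0.02,3
50S/50F,PV,1.01,0.05,3
40S/60F,PV,0.99,0.01,3
30S/70F,PV,0.77,0.01,3
20S/80F,PV,0.66,0.01,3
10S/90F,PV,0.64,0.01,3
0S/100F,PV,0.67,0.01,3
Control,PV,1.37,0.02,3
100S/0F,AnV,15.12,0.18,3
90S/10F,AnV,13.22,0.08,3
80S/20F,AnV,12.19,0.19,3
70S/30F,AnV,11.62,0.08,3
60S/40F,AnV,10.16,0.01,3
50S/50F,AnV,8.27,0.01,3
40S/60F,AnV,6.32,0.04,3
30S/70F,AnV,4.61,0.03,3
20S/80F,AnV,4.82,0.03,3
10S/90F,AnV,4.25,0.02,3
0S/100F,AnV,0,0,3
Control,AnV,3.42,0.02,3
100S/0F,TOTOX,18.32,0.19,3
90S/10F,TOTOX,16.24,0.03,3
80S/20F,TOTOX,15.11,0.19,3
70S/30F,TOTOX,14,0.09,3
60S/40F,TOTOX,12.56,0.04,3
50S/50F,TOTOX,10.28,0.1,3
40S/60F,TOTOX,8.3,0.06,3
30S/70F,TOTOX,6.14,0.02,3
20S/80F,TOTOX,6.13,0.03,3
10S/90F,TOTOX,5.52,0.02,3
0S/100F,TOTOX,1.33,0.02,3
Control,TOTOX,6.16,0.05,3
100S/0F,CD,2.39,0.06,3
90S/10F,CD,3.7,0.02,3
80S/20F,CD,3.66,0.1,3
70S/30F,CD,4.24,0.02,3
60S/40F,CD,4.39,0.08,3
50S/50F,CD,3.61,0.03,3
40S/60F,CD,3.33,0.12,3
30S/70F,CD,3.08,0.01,3
20S/80F,CD,2.85,0.05,3
10S/90F,CD,2.2,0.01,3
0S/100F,CD,2,0.01,3
Control,CD,2.6,0.01,3
100S/0F,CT,0.25,0.01,3
90S/10F,CT,0.38,0.01,3
80S/20F,CT,0.41,0.02,3
70S/30F,CT,0.62,0.01,3
60S/40F,CT,0.61,0.01,3
50S/50F,CT,0.42,0.02,3
40S/60F,CT,0.5,0.02,3
30S/70F,CT,0.34,0.01,3
20S/80F,CT,0.38,0.01,3
10S/90F,CT,0.17,0.01,3
0S/100F,CT,0.11,0.01,3
Control,CT,0.4,0.01,3
100S/0F,CD_CT,9.44,0.32,3
90S/10F,CD_CT,9.82,0.16,3
80S/20F,CD_CT,9.01,0.59,3
70S/30F,CD_CT,6.81,0.1,3
60S/40F,CD_CT,7.15,0.07,3
50S/50F,CD_CT,8.6,0.35,3
40S/60F,CD_CT,6.7,0.05,3
30S/70F,CD_CT,9.07,0.25,3
20S/80F,CD_CT,7.57,0.24,3
10S/90F,CD_CT,13.22,0.86,3
0S/100F,CD_CT,18.31,1.67,3
Control,CD_CT,6.56,0.09,3
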