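sample_id,variable,mean,sd,n
100S/0F,L,26.5,0.01,3
90S/10F,L,25.42,0.01,3
80S/20F,L,25.3,0.02,3
70S/30F,L,24.97,0.01,3
60S/40F,L,24.69,0,3
50S/50F,L,24.85,0.02,3
40S/60F,L,24.66,0.01,3
30S/70F,L,25,0.01,3
20S/80F,L,24.29,0.01,3
10S/90F,L,24.91,0.01,3
0S/100F,L,25.14,0.01,3
Control,L,25.48,0.02,3
100S/0F,a,-1,0.05,3
90S/10F,a,-2.13,0.1,3
80S/20F,a,-1.7,0.01,3
70S/30F,a,-1.19,0.02,3
60S/40F,a,-0.77,0.04,3
50S/50F,a,-0.4,0.06,3
40S/60F,a,-0.13,0.07,3
30S/70F,a,0.07,0.05,3
20S/80F,a,0.29,0.02,3
10S/90F,a,0.47,0.03,3
0S/100F,a,0.76,0.03,3
Control,a,-1.18,0.06,3
100S/0F,b,3.5,0.03,3
90S/10F,b,10.26,0.03,3
80S/20F,b,11.25,0.01,3
70S/30F,b,10.83,0.02,3
60S/40F,b,10.58,0.06,3
50S/50F,b,10.36,0.06,3
40S/60F,b,10.45,0.04,3
30S/70F,b,10.39,0.04,3
20S/80F,b,9.89,0.04,3
10S/90F,b,9.02,0.04,3
0S/100F,b,8.36,0.04,3
Control,b,4.25,0.02,3
100S/0F,deltaE,1.28,0.02,3
90S/10F,deltaE,6.08,0.02,3
80S/20F,deltaE,7.02,0.01,3
70S/30F,deltaE,6.6,0,3
60S/40F,deltaE,6.4,0.06,3
50S/50F,deltaE,6.19,0.05,3
40S/60F,deltaE,6.34,0.02,3
30S/70F,deltaE,6.28,0.04,3
20S/80F,deltaE,5.95,0.04,3
10S/90F,deltaE,5.08,0.03,3
0S/100F,deltaE,4.56,0.03,3
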