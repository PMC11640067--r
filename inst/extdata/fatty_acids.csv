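sample_id,variable,mean,sd,n
100S/0F,C14:0,nd,,3
90S/10F,C14:0,nd,,3
80S/20F,C14:0,nd,,3
70S/30F,C14:0,nd,,3
60S/40F,C14:0,nd,,3
50S/50F,C14:0,nd,,3
40S/60F,C14:0,nd,,3
30S/70F,C14:0,nd,,3
20S/80F,C14:0,nd,,3
10S/90F,C14:0,nd,,3
0S/100F,C14:0,nd,,3
Control,C14:0,nd,,3
100S/0F,C16:0,5.97,0,3
90S/10F,C16:0,5.84,0.01,3
80S/20F,C16:0,5.84,0.01,3
70S/30F,C16:0,6.08,0.01,3
60S/40F,C16:0,6,0.02,3
50S/50F,C16:0,5.56,0.01,3
40S/60F,C16:0,5.46,0.01,3
30S/70F,C16:0,5.28,0.01,3
20S/80F,C16:0,5.27,0.01,3
10S/90F,C16:0,5.18,0.03,3
0S/100F,C16:0,5,0.01,3
Control,C16:0,3.99,0,3
100S/0F,C16:1,0.08,0.01,3
90S/10F,C16:1,0.07,0,3
80S/20F,C16:1,0.07,0,3
70S/30F,C16:1,0.11,0.01,3
60S/40F,C16:1,0.08,0.01,3
50S/50F,C16:1,0.06,0.01,3
40S/60F,C16:1,0.06,0.01,3
30S/70F,C16:1,0.05,0.01,3
20S/80F,C16:1,0.06,0.01,3
10S/90F,C16:1,0.06,0.01,3
0S/100F,C16:1,0.04,0.01,3
Control,C16:1,0.11,0,3
100S/0F,C18:0,2.76,0,3
90S/10F,C18:0,2.93,0.01,3
80S/20F,C18:0,3.2,0,3
70S/30F,C18:0,3.4,0.01,3
60S/40F,C18:0,3.62,0.01,3
50S/50F,C18:0,3.61,0,3
40S/60F,C18:0,3.64,0,3
30S/70F,C18:0,3.83,0.01,3
20S/80F,C18:0,4,0.02,3
10S/90F,C18:0,4.11,0.01,3
0S/100F,C18:0,4.28,0.03,3
Control,C18:0,1.53,0,3
100S/0F,C18:1,30.25,0.05,3
90S/10F,C18:1,28.57,0.04,3
80S/20F,C18:1,27.36,0.02,3
70S/30F,C18:1,26.62,0.06,3
60S/40F,C18:1,26.13,0.03,3
50S/50F,C18:1,23.82,0.02,3
40S/60F,C18:1,22.37,0.02,3
30S/70F,C18:1,21.17,0.03,3
20S/80F,C18:1,19.38,0.58,3
10S/90F,C18:1,18.55,5.78,3
0S/100F,C18:1,17.02,0.02,3
Control,C18:1,64.21,0.01,3
100S/0F,C18:2n6,59.71,0.02,3
90S/10F,C18:2n6,57.18,0.06,3
80S/20F,C18:2n6,52.99,0.04,3
70S/30F,C18:2n6,48.34,0.01,3
60S/40F,C18:2n6,42.16,0.02,3
50S/50F,C18:2n6,40.13,0.01,3
40S/60F,C18:2n6,36.02,0.01,3
30S/70F,C18:2n6,32.04,0.02,3
20S/80F,C18:2n6,26.54,0.13,3
10S/90F,C18:2n6,23.56,0.01,3
0S/100F,C18:2n6,18.17,0.02,3
Control,C18:2n6,23.7,0.01,3
100S/0F,C18:3n6,nd,,3
90S/10F,C18:3n6,nd,,3
80S/20F,C18:3n6,nd,,3
70S/30F,C18:3n6,nd,,3
60S/40F,C18:3n6,nd,,3
50S/50F,C18:3n6,nd,,3
40S/60F,C18:3n6,0.08,0,3
30S/70F,C18:3n6,0.09,0,3
20S/80F,C18:3n6,0.11,0.01,3
10S/90F,C18:3n6,0.12,0.01,3
0S/100F,C18:3n6,0.14,0,3
Control,C18:3n6,nd,,3
100S/0F,C18:3n3,0.07,0.01,3
90S/10F,C18:3n3,4.33,0.02,3
80S/20F,C18:3n3,9.51,0.02,3
70S/30F,C18:3n3,14.48,0.02,3
60S/40F,C18:3n3,21.11,0.01,3
50S/50F,C18:3n3,26.02,0.01,3
40S/60F,C18:3n3,31.69,0.01,3
30S/70F,C18:3n3,36.93,0.05,3
20S/80F,C18:3n3,44.09,0.78,3
10S/90F,C18:3n3,47.88,0.05,3
0S/100F,C18:3n3,54.84,0.08,3
Control,C18:3n3,4.78,0.7,3
100S/0F,C20:0,0.19,0,3
90S/10F,C20:0,0.18,0.01,3
80S/20F,C20:0,0.18,0,3
70S/30F,C20:0,0.17,0.01,3
60S/40F,C20:0,0.18,0,3
50S/50F,C20:0,0.17,0,3
40S/60F,C20:0,0.15,0.01,3
30S/70F,C20:0,0.14,0.01,3
20S/80F,C20:0,0.13,0.01,3
10S/90F,C20:0,0.12,0.01,3
0S/100F,C20:0,0.12,0.01,3
Control,C20:0,0.4,0.01,3
100S/0F,C20:1,0.11,0,3
90S/10F,C20:1,0.11,0.01,3
80S/20F,C20:1,0.1,0,3
70S/30F,C20:1,0.13,0.01,3
60S/40F,C20:1,0.11,0,3
50S/50F,C20:1,0.1,0,3
40S/60F,C20:1,0.1,0,3
30S/70F,C20:1,0.09,0.01,3
20S/80F,C20:1,0.09,0.01,3
10S/90F,C20:1,0.09,0.01,3
0S/100F,C20:1,0.09,0,3
Control,C20:1,0.79,0.01,3
100S/0F,C22:0,0.6,0.03,3
90S/10F,C22:0,0.56,0.01,3
80S/20F,C22:0,0.51,0.01,3
70S/30F,C22:0,0.47,0.02,3
60S/40F,C22:0,0.44,0.02,3
50S/50F,C22:0,0.37,0.01,3
40S/60F,C22:0,0.3,0.01,3
30S/70F,C22:0,0.27,0.01,3
20S/80F,C22:0,0.21,0.01,3
10S/90F,C22:0,0.18,0.01,3
0S/100F,C22:0,0.15,0,3
Control,C22:0,0.31,0.02,3
100S/0F,C24:0,0.21,0.01,3
90S/10F,C24:0,0.22,0.01,3
80S/20F,C24:0,0.23,0.01,3
70S/30F,C24:0,0.19,0,3
60S/40F,C24:0,0.17,0,3
50S/50F,C24:0,0.16,0.01,3
40S/60F,C24:0,0.13,0.01,3
30S/70F,C24:0,0.11,0.01,3
20S/80F,C24:0,0.13,0,3
10S/90F,C24:0,0.14,0.01,3
0S/100F,C24:0,0.16,0.01,3
Control,C24:0,0.2,0.01,3
100S/0F,omega_ratio,892.91,,3
90S/10F,omega_ratio,13.19,,3
80S/20F,omega_ratio,5.57,,3
70S/30F,omega_ratio,3.34,,3
60S/40F,omega_ratio,2,,3
50S/50F,omega_ratio,1.54,,3
40S/60F,omega_ratio,1.14,,3
30S/70F,omega_ratio,0.87,,3
20S/80F,omega_ratio,0.6,,3
10S/90F,omega_ratio,0.49,,3
0S/100F,omega_ratio,0.33,,3
Control,omega_ratio,4.96,,3
100S/0F,IA,0.07,,3
90S/10F,IA,0.06,,3
80S/20F,IA,0.06,,3
70S/30F,IA,0.07,,3
60S/40F,IA,0.07,,3
50S/50F,IA,0.06,,3
40S/60F,IA,0.06,,3
30S/70F,IA,0.06,,3
20S/80F,IA,0.06,,3
10S/90F,IA,0.06,,3
0S/100F,IA,0.06,,3
Control,IA,0.04,,3
100S/0F,IT,0.19,,3
90S/10F,IT,0.16,,3
80S/20F,IT,0.13,,3
70S/30F,IT,0.12,,3
60S/40F,IT,0.1,,3
50S/50F,IT,0.08,,3
40S/60F,IT,0.07,,3
30S/70F,IT,0.07,,3
20S/80F,IT,0.06,,3
10S/90F,IT,0.06,,3
0S/100F,IT,0.05,,3
Control,IT,0.09,,3
100S/0F,HH,14.96,,3
90S/10F,HH,15.43,,3
80S/20F,HH,15.39,,3
70S/30F,HH,14.7,,3
60S/40F,HH,14.9,,3
50S/50F,HH,16.17,,3
40S/60F,HH,16.51,,3
30S/70F,HH,17.09,,3
20S/80F,HH,17.07,,3
10S/90F,HH,17.37,,3
0S/100F,HH,18.03,,3
Control,HH,23.26,,3
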