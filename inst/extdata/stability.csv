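sample_id,variable,mean,sd,n
100S/0F,rancimat_ip,9.48,0.14,3
90S/10F,rancimat_ip,9.05,0.15,3
80S/20F,rancimat_ip,8.46,0.12,3
70S/30F,rancimat_ip,7.92,0.08,3
60S/40F,rancimat_ip,7.41,0.07,3
50S/50F,rancimat_ip,6.93,0.06,3
40S/60F,rancimat_ip,6.38,0.08,3
30S/70F,rancimat_ip,5.83,0.05,3
20S/80F,rancimat_ip,5.25,0.11,3
10S/90F,rancimat_ip,4.77,0.09,3
0S/100F,rancimat_ip,4.28,0.08,3
Control,rancimat_ip,16.47,0.23,3
100S/0F,rapidoxy_ip,34.37,0.46,3
90S/10F,rapidoxy_ip,32.56,0.52,3
80S/20F,rapidoxy_ip,31.27,0.34,3
70S/30F,rapidoxy_ip,29.31,0.46,3
60S/40F,rapidoxy_ip,27.88,0.27,3
50S/50F,rapidoxy_ip,26.35,0.32,3
40S/60F,rapidoxy_ip,24.77,0.22,3
30S/70F,rapidoxy_ip,23.19,0.36,3
20S/80F,rapidoxy_ip,21.69,0.27,3
10S/90F,rapidoxy_ip,20,0.33,3
0S/100F,rapidoxy_ip,18.39,0.36,3
Control,rapidoxy_ip,70.5,0.84,3
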