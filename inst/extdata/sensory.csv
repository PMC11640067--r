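sample_id,variable,mean,sd,n
100S/0F,color_score,3.3,0.9,215
90S/10F,color_score,4.4,0.7,215
80S/20F,color_score,4.4,0.7,215
70S/30F,color_score,4.1,0.7,215
60S/40F,color_score,4.1,0.6,215
50S/50F,color_score,3.8,0.8,215
40S/60F,color_score,3.9,0.7,215
30S/70F,color_score,3.7,1.1,215
20S/80F,color_score,3.9,1.1,215
10S/90F,color_score,3.8,0.9,215
0S/100F,color_score,3.9,1,215
Control,color_score,3.6,0.9,215
100S/0F,odor_score,3.9,1.2,215
90S/10F,odor_score,3.6,1,215
80S/20F,odor_score,3.6,0.8,215
70S/30F,odor_score,3.7,0.8,215
60S/40F,odor_score,3.7,0.7,215
50S/50F,odor_score,3.7,0.9,215
40S/60F,odor_score,4.1,1,215
30S/70F,odor_score,3.9,0.7,215
20S/80F,odor_score,4.1,0.7,215
10S/90F,odor_score,4.2,0.5,215
0S/100F,odor_score,3.9,0.7,215
Control,odor_score,4.1,1.2,215
100S/0F,taste_score,4.1,1.4,215
90S/10F,taste_score,4.1,1,215
80S/20F,taste_score,3.9,1.1,215
70S/30F,taste_score,3.5,1,215
60S/40F,taste_score,3,1.1,215
50S/50F,taste_score,2.7,1.3,215
40S/60F,taste_score,2.4,1.5,215
30S/70F,taste_score,2.5,1.7,215
20S/80F,taste_score,2.3,1.9,215
10S/90F,taste_score,2.3,1.9,215
0S/100F,taste_score,2.6,2,215
Control,taste_score,3.9,1.1,215
100S/0F,average_rating,3.8,0.9,215
90S/10F,average_rating,4,0.6,215
80S/20F,average_rating,4,0.7,215
70S/30F,average_rating,3.8,0.7,215
60S/40F,average_rating,3.6,0.6,215
50S/50F,average_rating,3.4,0.7,215
40S/60F,average_rating,3.5,0.9,215
30S/70F,average_rating,3.4,0.9,215
20S/80F,average_rating,3.4,0.8,215
10S/90F,average_rating,3.4,0.7,215
0S/100F,average_rating,3.5,0.9,215
Control,average_rating,3.9,0.9,215
100S/0F,total_acceptability,3.8,1,215
90S/10F,total_acceptability,4,0.7,215
80S/20F,total_acceptability,3.9,0.7,215
70S/30F,total_acceptability,3.7,0.7,215
60S/40F,total_acceptability,3.5,0.6,215
50S/50F,total_acceptability,3.3,0.8,215
40S/60F,total_acceptability,3.3,1,215
30S/70F,total_acceptability,3.3,1,215
20S/80F,total_acceptability,3.3,0.9,215
10S/90F,total_acceptability,3.3,0.9,215
0S/100F,total_acceptability,3.4,1,215
Control,total_acceptability,3.9,0.9,215
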