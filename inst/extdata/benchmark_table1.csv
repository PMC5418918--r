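# Published per-channel signal-quality benchmark for the 5 simultaneous
# direct + 4-channel abdominal labor records of the PhysioNet "Abdominal
# and Direct Fetal Electrocardiogram Database" (60 s, 1000 Hz).
# Amplitudes in microvolts; SNRs in dB; rho is Pearson correlation between
# the direct and indirect fetal ECG estimates.
record,channel,dfecg_uv,dn_uv,dsnr_db,ifecg_uv,in_uv,isnr1_db,isnr2_db,rho
1,1,104,34,4.9,18,14,1.0,11.2,0.85
1,2,104,34,4.9,23,30,-1.2,9.6,0.79
1,3,104,34,4.9,21,15,1.5,11.1,0.87
1,4,104,34,4.9,35,34,0.1,11.0,0.89
2,1,87,41,3.3,5,72,-11.7,4.8,0.63
2,2,87,41,3.3,20,106,-7.3,9.6,0.82
2,3,87,41,3.3,13,94,-8.7,7.9,0.81
2,4,87,41,3.3,20,114,-7.5,9.1,0.75
3,1,89,73,0.9,5,70,-11.1,6.0,0.45
3,2,89,73,0.9,18,77,-6.4,8.0,0.77
3,3,89,73,0.9,11,76,-8.4,7.9,0.75
3,4,89,73,0.9,22,83,-5.8,9.6,0.80
4,1,208,70,4.8,24,56,-3.8,9.9,0.83
4,2,208,70,4.8,29,55,-2.8,10.0,0.76
4,3,208,70,4.8,25,31,-0.9,10.4,0.83
4,4,208,70,4.8,43,43,0,10.8,0.87
5,1,140,94,1.8,54,26,3.2,11.7,0.77
5,2,140,94,1.8,41,24,2.3,10.9,0.76
5,3,140,94,1.8,10,16,-1.8,7.6,0.28
5,4,140,94,1.8,28,19,1.5,9.5,0.59
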