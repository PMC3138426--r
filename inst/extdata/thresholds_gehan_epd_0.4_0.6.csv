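r_alt,r_nul,epd_alt,epd_nul,n1,n2,s_r,s_p,a_r,a_p
0.2,0.05,0.4,0.6,14,1,1,8,2,7
0.2,0.05,0.4,0.6,14,3,1,8,2,9
0.2,0.05,0.4,0.6,14,4,1,8,3,9
0.2,0.05,0.4,0.6,14,5,1,8,3,9
0.2,0.05,0.4,0.6,14,6,1,8,3,9
0.2,0.05,0.4,0.6,14,9,1,8,3,11
0.2,0.05,0.4,0.6,14,10,1,8,3,12
0.2,0.05,0.4,0.6,14,11,1,8,4,12
0.2,0.05,0.4,0.6,14,13,1,8,4,14
0.2,0.05,0.4,0.6,14,15,1,8,4,14
0.2,0.05,0.4,0.6,14,16,1,8,4,14
0.2,0.05,0.4,0.6,14,18,1,8,4,16
0.2,0.05,0.4,0.6,14,20,1,8,5,17
0.2,0.05,0.4,0.6,14,21,1,8,5,17
0.2,0.05,0.4,0.6,14,22,1,8,5,19
0.2,0.05,0.4,0.6,14,23,1,8,5,19
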