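r_alt,r_nul,epd_alt,epd_nul,n1,n2,s_r,s_p,a_r,a_p
0.2,0.05,0.3,0.5,14,1,1,6,2,5
0.2,0.05,0.3,0.5,14,3,1,6,3,7
0.2,0.05,0.3,0.5,14,4,1,6,3,7
0.2,0.05,0.3,0.5,14,5,1,6,3,7
0.2,0.05,0.3,0.5,14,6,1,6,3,7
0.2,0.05,0.3,0.5,14,9,1,6,3,9
0.2,0.05,0.3,0.5,14,10,1,6,4,9
0.2,0.05,0.3,0.5,14,11,1,6,3,9
0.2,0.05,0.3,0.5,14,13,1,6,4,11
0.2,0.05,0.3,0.5,14,15,1,6,4,11
0.2,0.05,0.3,0.5,14,16,1,6,4,11
0.2,0.05,0.3,0.5,14,18,1,6,4,13
0.2,0.05,0.3,0.5,14,20,1,6,5,13
0.2,0.05,0.3,0.5,14,21,1,6,5,13
0.2,0.05,0.3,0.5,14,22,1,6,5,15
0.2,0.05,0.3,0.5,14,23,1,6,5,15
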