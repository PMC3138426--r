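r_alt,r_nul,epd_alt,epd_nul,n1,n2,s_r,s_p,a_r,a_p
0.2,0.05,0.4,0.6,15,15,1,8,4,14
0.2,0.05,0.3,0.5,15,15,1,6,4,11
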