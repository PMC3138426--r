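trial_id,n1,r1,p1,n_tot,r_tot,p_tot,investigator_stopped
1,15,0,6,,,,FALSE
2,15,0,1,,,,FALSE
3,15,0,10,,,,FALSE
4,15,0,7,,,,FALSE
5,15,0,9,,,,FALSE
6,15,0,14,,,,FALSE
7,14,0,7,,,,FALSE
8,15,0,6,,,,FALSE
9,15,0,3,,,,FALSE
10,15,0,12,,,,FALSE
11,15,1,9,,,,TRUE
12,15,7,6,30,13,13,FALSE
13,15,1,6,25,1,12,FALSE
14,15,1,6,30,3,13,FALSE
15,15,2,4,30,2,8,FALSE
16,15,1,6,29,4,12,FALSE
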