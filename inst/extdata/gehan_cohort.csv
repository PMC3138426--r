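trial_id,n1,r1,p1,n_tot,r_tot,p_tot,investigator_stopped
1,14,0,14,23,0,20,FALSE
2,14,0,10,24,0,18,FALSE
3,14,0,9,17,0,10,FALSE
4,14,0,8,36,0,23,FALSE
5,14,0,11,19,0,14,FALSE
6,14,0,13,23,0,20,FALSE
7,14,0,11,15,0,12,FALSE
8,14,0,11,,,,FALSE
9,14,1,12,34,2,23,FALSE
10,14,1,8,27,2,16,FALSE
11,14,1,10,19,1,12,FALSE
12,14,1,10,25,2,17,FALSE
13,14,1,10,20,1,15,FALSE
14,14,1,9,17,1,11,FALSE
15,14,1,12,18,1,16,FALSE
16,14,4,9,29,7,14,FALSE
17,14,8,2,34,20,3,FALSE
18,14,5,4,32,7,13,FALSE
19,14,4,4,37,12,14,FALSE
20,14,4,3,30,7,11,FALSE
21,14,5,4,36,9,9,FALSE
22,14,3,4,27,6,10,FALSE
23,14,11,1,35,27,3,FALSE
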