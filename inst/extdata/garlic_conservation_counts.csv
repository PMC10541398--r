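group,sample_a,sample_b,n_variable,n_conserved_het,percent_printed,is_replicate
A,26,39,12344,5574,45.1,FALSE
A,34,36,15116,6166,40.8,FALSE
A,35,39,11135,4961,44.5,FALSE
A,35,42,17896,6545,36.6,FALSE
A,39,34,9726,5065,52.1,FALSE
A,39,35,11015,5078,46.1,FALSE
A,42,34,14962,5987,40.0,FALSE
B,2,8,6160,2810,45.6,FALSE
B,2,21,9316,3695,39.6,FALSE
B,8,12,10640,4336,40.7,FALSE
B,8,27,7444,3702,49.7,FALSE
B,12,14,22672,10740,47.4,FALSE
B,14,15,16321,7997,49.0,TRUE
B,30,31,14445,6882,47.6,TRUE
C1,4,5,11062,1644,14.9,FALSE
C1,10,22,10348,4981,48.1,FALSE
C1,22,44,24017,4014,16.7,FALSE
C1,33,43,34734,5058,14.6,FALSE
C1,43,4,19758,2748,13.9,FALSE
C1,48,4,7961,4030,50.7,FALSE
C1,49,4,11033,2402,21.8,FALSE
C2,7,11,13991,3218,23.0,FALSE
C2,7,23,15078,3307,21.9,FALSE
C2,11,23,15539,4533,29.2,FALSE
C2,11,24,13055,7026,53.8,FALSE
C2,23,24,16974,4967,29.3,FALSE
C2,24,7,15418,3432,22.2,FALSE
C3,1,3,13815,5548,40.1,FALSE
C3,3,20,20615,3629,17.6,FALSE
C3,16,20,25155,5146,20.4,FALSE
C3,18,41,12343,2167,17.5,FALSE
C3,37,45,11183,2933,26.2,FALSE
C3,45,1,13057,2782,21.3,FALSE
C3,46,16,25504,6161,24.1,FALSE
C4,6,13,24481,3843,15.7,FALSE
C4,13,28,26763,3199,11.9,FALSE
C4,17,32,12418,5361,43.9,TRUE
C4,19,38,20175,2568,12.7,FALSE
C4,29,47,3007,431,14.3,FALSE
C4,47,6,2473,136,5.4,FALSE
C4,50,6,12063,2425,20.1,FALSE
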