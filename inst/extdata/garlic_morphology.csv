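sample_id,group,n_leaves,n_tillers,leaf_length,leaf_width,sheath_diameter,n_daughter_bulbs,bulb_weight_total,bulb_weight_max,bulb_diameter_max
39,A,7.3,2.5,44.8,5.1,8.5,16.7,19.8,3.9,19.7
26,A,10.4,2.0,58.0,6.9,10.5,15.6,30.2,7.7,23.8
42,A,9.3,3.4,58.7,7.8,12.5,16.9,31.5,6.4,22.1
2,B,8.4,4.0,61.4,7.9,12.9,6.0,22.1,11.4,26.8
12,B,9.9,4.1,58.9,9.6,16.2,5.6,23.6,10.6,26.9
14,B,9.1,3.0,56.9,8.2,14.4,5.0,24.3,13.3,28.6
27,B,9.4,4.3,56.0,8.5,11.3,4.6,12.2,6.9,22.6
5,C1,5.1,1.5,45.7,6.2,7.4,3.4,8.5,4.9,19.5
4,C1,7.6,1.9,49.3,8.0,14.6,4.7,15.9,7.9,23.9
9,C1,8.5,1.8,49.4,7.6,10.3,4.6,17.1,7.3,24.2
23,C2,9.4,2.5,62.3,6.3,12.0,9.2,44.6,16.4,31.4
7,C2,9.4,2.0,38.5,5.3,9.9,14.0,27.2,4.8,21.3
18,C3,9.2,8.5,54.5,8.7,13.9,76.3,70.3,5.6,21.5
16,C3,7.5,3.5,45.3,7.1,13.6,6.1,33.6,14.3,29.6
1,C3,8.0,5.8,52.2,8.1,10.0,10.9,24.4,5.8,22.0
20,C3,12.0,5.5,51.8,7.9,15.6,13.2,30.1,5.4,20.9
40,C4,9.1,5.4,53.7,8.5,14.9,18.7,45.9,8.4,24.9
38,C4,8.2,3.3,51.0,7.5,13.3,20.8,50.3,7.3,22.8
28,C4,9.7,6.1,69.6,6.8,13.9,13.6,44.7,8.7,25.2
17,C4,7.2,2.3,53.5,6.3,11.0,14.7,32.6,7.1,25.0
6,C4,10.7,6.2,76.0,8.1,10.6,27.0,57.6,9.7,25.0
19,C4,11.2,4.4,61.5,7.4,13.9,16.7,61.3,9.4,27.0
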