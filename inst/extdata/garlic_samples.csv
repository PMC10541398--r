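sample_id,region_label,replicate_of,group
1,Kinki,,C3
2,Kanto,,B
3,Shikoku,,C3
4,Shikoku,,C1
5,Tohoku,,C1
6,Kinki,,C4
7,Chubu,,C2
8,Chubu,,B
9,Kinki,,C1
10,Tohoku,,C1
11,Chubu,,C2
12,Kanto,,B
13,Kinki,,C4
14,Shikoku,,B
15,Shikoku,14,B
16,Kyushu,,C3
17,Okinawa,,C4
18,Chubu,,C3
19,Chugoku,,C4
20,Chugoku,,C3
21,Tohoku,,B
22,Tohoku,,C1
23,Chubu,,C2
24,Tohoku,,C2
25,Kanto,,B
26,Shikoku,,A
27,Kinki,,B
28,Kyushu,,C4
29,Kanto,,C4
30,Kanto,,B
31,Kanto,30,B
32,Okinawa,17,C4
33,Tohoku,,C1
34,Shikoku,,A
35,Chugoku,,A
36,Shikoku,,A
37,Kyushu,,C3
38,Kyushu,,C4
39,Kyushu,,A
40,Kyushu,,C4
41,Kyushu,,C3
42,Chugoku,,A
43,Kyushu,,C1
44,Kyushu,,C1
45,Kyushu,,C3
46,Kyushu,,C3
47,Kinki,,C4
48,Kanto,,C1
49,Chubu,,C1
50,Kyushu,,C4
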