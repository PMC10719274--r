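item,subscale,reverse
1,non_planning,1
2,motor,0
3,motor,0
4,motor,0
5,attentional,0
6,attentional,0
7,non_planning,1
8,non_planning,1
9,attentional,1
10,non_planning,1
11,attentional,0
12,non_planning,1
13,non_planning,1
14,non_planning,0
15,non_planning,1
16,motor,0
17,motor,0
18,non_planning,0
19,motor,0
20,attentional,1
21,motor,0
22,motor,0
23,motor,0
24,attentional,0
25,motor,0
26,attentional,0
27,non_planning,0
28,attentional,0
29,non_planning,1
30,motor,1
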