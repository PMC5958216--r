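# study Q-matrix fixture: 31 items x 5 attributes, versioned (synthetic, paper matrix unpublished)
item,1,2,3,4,5
1,0,0,0,1,0
2,1,0,0,0,0
3,0,1,0,0,0
4,0,0,1,0,0
5,0,0,0,0,1
6,1,0,0,0,0
7,0,1,0,0,0
8,0,0,1,0,0
9,0,0,0,1,0
10,0,0,0,0,1
11,1,1,0,0,0
12,0,1,1,0,0
13,0,0,1,1,0
14,0,0,0,1,1
15,1,0,0,0,1
16,1,0,1,0,0
17,0,1,0,1,0
18,0,0,1,0,1
19,1,1,1,0,0
20,0,1,1,1,0
21,0,0,1,1,1
22,1,0,0,1,1
23,1,1,0,0,1
24,1,0,1,1,0
25,0,1,0,1,1
26,1,1,1,1,0
27,0,1,1,1,1
28,1,0,1,1,1
29,1,1,0,1,1
30,1,1,1,1,1
31,1,1,1,1,1
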