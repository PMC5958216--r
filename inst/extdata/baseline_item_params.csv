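# frozen baseline slipping/guessing draw, U[0.1,0.3], seed 11364
item,slipping,guessing
1,0.195025999424979,0.172226626006886
2,0.231601424235851,0.297629227815196
3,0.278645192878321,0.195191374048591
4,0.124255703110248,0.269434089493006
5,0.291099139163271,0.22377198911272
6,0.273356297938153,0.190993649233133
7,0.221956666465849,0.202889283234254
8,0.298155566817149,0.235886134812608
9,0.191681480687112,0.154326225304976
10,0.143011445552111,0.239668247383088
11,0.193169218534604,0.207449171599001
12,0.145431054849178,0.196038437774405
13,0.239574399311095,0.121687195589766
14,0.237433089502156,0.157209659460932
15,0.213646494923159,0.127069147722796
16,0.197716419724748,0.160425197379664
17,0.288254973106086,0.198354113753885
18,0.234778411500156,0.137072759913281
19,0.260691739199683,0.174605853110552
20,0.218879596702754,0.256786773214117
21,0.257556335814297,0.200352338561788
22,0.255193093512207,0.145720634935424
23,0.101971577340737,0.248755746195093
24,0.295100162969902,0.126692840736359
25,0.134375926339999,0.10298678977415
26,0.276921346830204,0.119818726927042
27,0.245369176892564,0.200504029309377
28,0.275286433426663,0.178842804394662
29,0.254471718333662,0.164889871608466
30,0.243167287483811,0.105788993090391
31,0.256117166904733,0.124745444068685
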