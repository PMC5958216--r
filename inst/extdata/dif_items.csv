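# frozen DIF item ids, stratified 3 low / 3 high complexity, seed 20180511
item
9
12
13
20
22
23
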