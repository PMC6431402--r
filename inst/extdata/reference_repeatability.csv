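dataset,r1,r2,r3,r4,r5,r6,r7,r8,r9,r10
1,100,87.5,87.5,87.5,87.5,87.5,100,87.5,100,75
2,100,100,100,100,87.5,100,87.5,87.5,87.5,75
3,100,87.5,87.5,100,87.5,100,100,100,100,87.5
4,87.5,87.5,75,87.5,87.5,87.5,87.5,87.5,87.5,100
5,87.5,87.5,87.5,100,100,100,100,87.5,87.5,100
6,100,87.5,87.5,100,87.5,75,87.5,100,87.5,100
7,100,100,100,87.5,100,100,100,100,87.5,100
8,87.5,87.5,75,87.5,87.5,87.5,87.5,87.5,87.5,87.5
9,87.5,100,75,87.5,87.5,100,87.5,87.5,75,87.5
10,100,100,100,100,87.5,100,100,100,100,100
11,87.5,100,100,87.5,100,87.5,100,87.5,100,87.5
12,87.5,87.5,75,87.5,87.5,87.5,87.5,87.5,75,87.5
13,87.5,87.5,87.5,75,87.5,87.5,75,87.5,87.5,87.5
14,100,87.5,100,87.5,87.5,87.5,100,87.5,87.5,87.5
15,87.5,87.5,87.5,100,87.5,100,87.5,87.5,87.5,100
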