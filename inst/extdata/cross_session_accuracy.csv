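subject,m1d1,m1d2,m2d1,m2d2
1,97.40,98.96,96.88,99.48
2,100,68.75,84.90,94.27
3,100,94.27,98.96,98.96
4,99.48,99.48,98.44,99.48
5,98.44,82.29,96.35,96.88
6,75.00,25.52,2.08,70.83
7,99.48,98.96,99.48,100
8,99.48,96.88,92.71,100
9,79.17,4.69,11.98,89.06
10,100,96.88,91.67,96.35
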