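value
0.77
1.74
0.81
1.20
1.95
1.20
0.47
1.43
3.37
2.20
3.00
3.09
1.51
2.10
0.52
1.62
1.31
0.32
0.59
0.81
2.81
1.87
1.18
1.35
4.75
2.48
0.96
1.89
0.90
2.05
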