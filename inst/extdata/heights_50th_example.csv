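age,height_cm
0.1,54.7
0.5,67.0
1,75.7
2,86.9
3,95.3
5,109.2
8,128.1
10,138.4
15,167.4
18,176.1
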