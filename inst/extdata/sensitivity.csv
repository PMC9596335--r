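code,habitat,arable,reservoir,urban,rural_settlements,other_construction
1,0,0,0,0,0,0
3,0,0,0,0,0,0
6,0,0,0,0,0,0
21,0.8,0.8,0.5,0.7,0.7,0.5
22,1,0.9,0.6,0.7,0.8,0.6
23,0.6,0.5,0.6,0.6,0.8,0.4
24,0.1,0.3,0.4,0.2,0.2,0.3
41,1,0.9,0.9,0.7,0.7,0.6
43,0,0,0,0,0,0
45,0,0,0,0,0,0
46,0,0,0,0,0,0
51,0,0,0,0,0,0
52,0,0,0,0,0,0
53,0,0,0,0,0,0
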