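growth_rate	uptake_rate
0.1	0.2
0.15	0.3
0.2	0.4
0.25	0.5
0.3	0.6
0.35	0.7
0.4	0.8
0.45	0.9
0.5	1
0.55	1.1
0.65	1.45
0.7	1.7
0.75	1.95
0.8	2.2
0.85	2.45
0.9	2.7
0.95	2.95
1	3.2
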