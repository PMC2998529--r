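gene_a	gene_b	max	bma
g1	g2	0.6666666667	0.5555555556
g1	g3	0.3333333333	0.3333333333
g1	g4	0.2260239684	0.2260239684
g1	g5	0.0000000000	0.0000000000
g1	g6	0.0000000000	0.0000000000
g1	g7	0.0000000000	0.0000000000
g1	g8	0.3333333333	0.2222222222
g2	g3	0.3333333333	0.3333333333
g2	g4	0.2260239684	0.2260239684
g2	g5	0.0000000000	0.0000000000
g2	g6	0.0000000000	0.0000000000
g2	g7	0.0000000000	0.0000000000
g2	g8	0.6666666667	0.4166666667
g3	g4	0.2260239684	0.2260239684
g3	g5	0.0000000000	0.0000000000
g3	g6	0.0000000000	0.0000000000
g3	g7	0.0000000000	0.0000000000
g3	g8	0.3333333333	0.2222222222
g4	g5	0.0000000000	0.0000000000
g4	g6	0.0000000000	0.0000000000
g4	g7	0.0000000000	0.0000000000
g4	g8	0.2260239684	0.1506826456
g5	g6	0.4716791664	0.4716791664
g5	g7	0.4716791664	0.4716791664
g5	g8	0.3333333333	0.2222222222
g6	g7	0.4716791664	0.4716791664
g6	g8	0.6666666667	0.4444444444
g7	g8	0.3333333333	0.2222222222
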