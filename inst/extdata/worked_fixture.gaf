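!gaf-version: 2.1
! synthetic worked fixture annotations: 8 genes over the 14-term ontology
SYN	g1	G1P		GO:0000009	SYN:0000001	IDA		C	gene one		protein	taxon:4932	20100101	SYN
SYN	g2	G2P		GO:0000009	SYN:0000001	IDA		C	gene two		protein	taxon:4932	20100101	SYN
SYN	g2	G2P		GO:0000010	SYN:0000001	IMP		C	gene two		protein	taxon:4932	20100101	SYN
SYN	g3	G3P		GO:0000007	SYN:0000001	IDA		C	gene three		protein	taxon:4932	20100101	SYN
SYN	g4	G4P		GO:0000008	SYN:0000001	IDA		C	gene four		protein	taxon:4932	20100101	SYN
SYN	g5	G5P		GO:0000013	SYN:0000001	IDA		C	gene five		protein	taxon:4932	20100101	SYN
SYN	g6	G6P		GO:0000014	SYN:0000001	IDA		C	gene six		protein	taxon:4932	20100101	SYN
SYN	g7	G7P		GO:0000011	SYN:0000001	IDA		C	gene seven		protein	taxon:4932	20100101	SYN
SYN	g8	G8P		GO:0000012	SYN:0000001	IDA		C	gene eight		protein	taxon:4932	20100101	SYN
SYN	g8	G8P		GO:0000010	SYN:0000001	IMP		C	gene eight		protein	taxon:4932	20100101	SYN
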