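term	ict	ica	icm	ics	subgraphs
GO:0000001	0.0000000000	0.0000000000	0.0000000000	1.0000000000	GO:0000001
GO:0000002	0.8472978604	0.4700036292	0.6780719051	1.0000000000	GO:0000002
GO:0000003	0.6931471806	0.6931471806	1.0000000000	1.0000000000	GO:0000003
GO:0000004	0.8472978604	0.6931471806	1.0000000000	1.0000000000	GO:0000004
GO:0000005	1.0296194172	0.4700036292	0.6780719051	0.2260239684	GO:0000005
GO:0000006	1.0296194172	0.6931471806	1.0000000000	0.3333333333	GO:0000006
GO:0000007	1.5404450409	0.6931471806	NA	0.3333333333	GO:0000005
GO:0000008	2.6390573296	2.0794415417	NA	1.0000000000	GO:0000005
GO:0000009	2.6390573296	1.3862943611	NA	0.6666666667	GO:0000005
GO:0000010	2.6390573296	1.3862943611	NA	0.6666666667	GO:0000005
GO:0000011	1.5404450409	0.9808292530	NA	0.4716791664	GO:0000006
GO:0000012	1.9459101491	1.3862943611	NA	0.6666666667	GO:0000006
GO:0000013	2.6390573296	2.0794415417	NA	1.0000000000	GO:0000006
GO:0000014	2.6390573296	2.0794415417	NA	1.0000000000	GO:0000006
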