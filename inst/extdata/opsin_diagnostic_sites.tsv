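exon	base_a	base_b	pos_a	pos_b	exon_pos	genome_pos_a	genome_pos_b
2	C	T	254	276	81	154150737	154187851
2	A	G	360	382	187	154150843	154187957
2	A	G	391	413	218	154150874	154187988
2	C	A	407	429	234	154150890	154188004
4	T	C	749	771	110	154154684	154191798
4	G	A	757	779	118	154154692	154191806
4	C	G	758	780	119	154154693	154191807
4	T	C	759	781	120	154154694	154191808
4	A	G	766	788	127	154154701	154191815
5	A	G	880	902	75	154156369	154193483
5	T	C	883	905	78	154156372	154193486
5	T	G	885	907	80	154156374	154193488
5	G	A	888	910	83	154156377	154193491
5	A	T	890	912	85	154156379	154193493
5	G	T	895	917	90	154156384	154193498
5	C	A	901	931	104	154156398	154193512
5	A	G	905	935	108	154156402	154193516
5	T	C	940	970	143	154156437	154193551
5	G	C	944	974	147	154156441	154193555
5	A	T	978	1008	181	154156475	154193589
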