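tumor_id	variant	gene	category	vaf
5128	T5506C	ND2	missense	91
5139	T11875C	ND4	silent	92
5139	G13531A	ND5	missense	93
5150	G4308A	TRNI	tRNA	46
5155	G14410A	ND6	silent	35
5157	C14112T	ND5	silent	96
5160	T152C	CR	noncoding	88
5160	G1642A	TRNV	tRNA	80
5160	G13417A	ND5	nonsense	51
5161	G5560A	TRNW	tRNA	12
5163	T9062C	ATP6	missense	14
5165	G529A	CR	noncoding	99
5165	G2553A	RNR2	rRNA	17
5165	G5753A	O_L	noncoding	98
5165	G14453A	ND6	missense	98
5167	T14325C	ND6	missense	94
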