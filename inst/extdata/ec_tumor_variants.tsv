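tumor_id	variant	gene	category	vaf	coverage
P1	C5899CC	NC5	noncoding	26	714
P1	T6481C	COX1	missense	71	794
P1	T9179C	ATP6	missense	69	767
P1	G15995A	TRNP	tRNA	64	756
P1	C16327T	CR	noncoding	64	489
P2	G12007A	ND4	silent	75	424
P2	T13490C	ND5	missense	94	516
P3	G10401A	ND3	missense	66	556
P3	A10411T	TRNR	tRNA	63	540
P3	G10644A	ND4L	missense	67	658
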