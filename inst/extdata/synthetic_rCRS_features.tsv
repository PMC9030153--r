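name	kind	start	end	strand	frame	incomplete_stop	overlap_ok
CR	noncoding	1	576	-	0	FALSE	FALSE
TRNF	tRNA	577	647	H	0	FALSE	FALSE
RNR1	rRNA	648	1601	H	0	FALSE	FALSE
TRNV	tRNA	1602	1670	H	0	FALSE	FALSE
RNR2	rRNA	1671	3229	H	0	FALSE	FALSE
TRNL1	tRNA	3230	3304	H	0	FALSE	FALSE
NC1	noncoding	3305	3306	-	0	FALSE	FALSE
ND1	protein	3307	4262	H	0	TRUE	FALSE
TRNI	tRNA	4263	4331	H	0	FALSE	FALSE
TRNQ	tRNA	4329	4400	L	0	FALSE	FALSE
NC2	noncoding	4401	4401	-	0	FALSE	FALSE
TRNM	tRNA	4402	4469	H	0	FALSE	FALSE
ND2	protein	4470	5511	H	0	TRUE	FALSE
TRNW	tRNA	5512	5579	H	0	FALSE	FALSE
NC3	noncoding	5580	5586	-	0	FALSE	FALSE
TRNA	tRNA	5587	5655	L	0	FALSE	FALSE
NC4	noncoding	5656	5656	-	0	FALSE	FALSE
TRNN	tRNA	5657	5729	L	0	FALSE	FALSE
O_L	noncoding	5721	5798	-	0	FALSE	FALSE
TRNC	tRNA	5761	5826	L	0	FALSE	FALSE
TRNY	tRNA	5826	5891	L	0	FALSE	FALSE
NC5	noncoding	5892	5903	-	0	FALSE	FALSE
COX1	protein	5904	7445	H	0	FALSE	FALSE
TRNS1	tRNA	7446	7514	L	0	FALSE	FALSE
NC6	noncoding	7515	7517	-	0	FALSE	FALSE
TRND	tRNA	7518	7585	H	0	FALSE	FALSE
COX2	protein	7586	8269	H	0	FALSE	FALSE
NC7	noncoding	8270	8294	-	0	FALSE	FALSE
TRNK	tRNA	8295	8364	H	0	FALSE	FALSE
NC8	noncoding	8365	8365	-	0	FALSE	FALSE
ATP8	protein	8366	8572	H	0	FALSE	TRUE
ATP6	protein	8527	9207	H	0	FALSE	TRUE
COX3	protein	9207	9990	H	0	TRUE	TRUE
TRNG	tRNA	9991	10058	H	0	FALSE	FALSE
ND3	protein	10059	10404	H	0	TRUE	FALSE
TRNR	tRNA	10405	10469	H	0	FALSE	FALSE
ND4L	protein	10470	10766	H	0	FALSE	TRUE
ND4	protein	10760	12137	H	0	TRUE	TRUE
TRNH	tRNA	12138	12206	H	0	FALSE	FALSE
TRNS2	tRNA	12207	12265	H	0	FALSE	FALSE
TRNL2	tRNA	12266	12336	H	0	FALSE	FALSE
ND5	protein	12337	14148	H	0	FALSE	FALSE
ND6	protein	14149	14673	L	0	FALSE	FALSE
TRNE	tRNA	14674	14742	L	0	FALSE	FALSE
NC9	noncoding	14743	14746	-	0	FALSE	FALSE
CYB	protein	14747	15887	H	0	TRUE	FALSE
TRNT	tRNA	15888	15953	H	0	FALSE	FALSE
NC10	noncoding	15954	15955	-	0	FALSE	FALSE
TRNP	tRNA	15956	16023	L	0	FALSE	FALSE
CR	noncoding	16024	16569	-	0	FALSE	FALSE
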