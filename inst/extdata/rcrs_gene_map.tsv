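name	start	end	strand	category	complex	incomplete_stop
DLOOP	16024	576	H	dloop	.	0
TRNF	577	647	H	tRNA	.	0
RNR1	648	1601	H	rRNA	.	0
TRNV	1602	1670	H	tRNA	.	0
RNR2	1671	3229	H	rRNA	.	0
TRNL1	3230	3304	H	tRNA	.	0
NC1	3305	3306	H	intergenic	.	0
ND1	3307	4262	H	protein	I	2
TRNI	4263	4331	H	tRNA	.	0
TRNQ	4329	4400	L	tRNA	.	0
NC2	4401	4401	H	intergenic	.	0
TRNM	4402	4469	H	tRNA	.	0
ND2	4470	5511	H	protein	I	1
TRNW	5512	5579	H	tRNA	.	0
NC3	5580	5586	H	intergenic	.	0
TRNA	5587	5655	L	tRNA	.	0
NC4	5656	5656	H	intergenic	.	0
TRNN	5657	5729	L	tRNA	.	0
OLR1	5721	5798	L	regulatory	.	0
TRNC	5761	5826	L	tRNA	.	0
TRNY	5826	5891	L	tRNA	.	0
NC5	5892	5903	H	intergenic	.	0
CO1	5904	7445	H	protein	IV	0
TRNS1	7446	7514	L	tRNA	.	0
NC6	7515	7517	H	intergenic	.	0
TRND	7518	7585	H	tRNA	.	0
CO2	7586	8269	H	protein	IV	1
NC7	8270	8294	H	intergenic	.	0
TRNK	8295	8364	H	tRNA	.	0
NC8	8365	8365	H	intergenic	.	0
ATP8	8366	8572	H	protein	V	0
ATP6	8527	9207	H	protein	V	0
CO3	9207	9990	H	protein	IV	1
TRNG	9991	10058	H	tRNA	.	0
ND3	10059	10404	H	protein	I	1
TRNR	10405	10469	H	tRNA	.	0
ND4L	10470	10766	H	protein	I	0
ND4	10760	12137	H	protein	I	1
TRNH	12138	12206	H	tRNA	.	0
TRNS2	12207	12265	H	tRNA	.	0
TRNL2	12266	12336	H	tRNA	.	0
ND5	12337	14148	H	protein	I	0
ND6	14149	14673	L	protein	I	0
TRNE	14674	14742	L	tRNA	.	0
NC9	14743	14746	H	intergenic	.	0
CYB	14747	15887	H	protein	III	1
TRNT	15888	15953	H	tRNA	.	0
NC10	15954	15955	H	intergenic	.	0
TRNP	15956	16023	L	tRNA	.	0
LPS	192	445	L	regulatory	.	0
TAS	16157	16172	H	regulatory	.	0
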