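haplogroup	position	ref	alt
A	663	A	G
A	1736	A	G
A	4248	T	C
A	4824	A	G
A	8794	C	T
A	16290	C	T
A	16319	G	A
B	827	A	G
B	4977	T	C
B	6473	C	T
B	9950	T	C
B	16217	T	C
C	3552	T	A
C	9545	A	G
C	13263	A	G
C	14318	T	C
C	16327	C	T
D	4883	C	T
D	5178	C	A
D	8414	C	T
D	14668	C	T
D	16362	T	C
H	456	C	T
H	2706	A	G
H	3992	C	T
H	6776	T	C
H	7028	C	T
J	295	C	T
J	489	T	C
J	12612	A	G
J	13708	G	A
J	16069	C	T
L	2758	G	A
L	3594	C	T
L	7256	C	T
L	13650	C	T
L	16187	C	T
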