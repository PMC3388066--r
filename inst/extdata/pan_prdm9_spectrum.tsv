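group	allele	count	aa_allele
eastern	p1	6	P1
eastern	p2	1	P2
eastern	p3	1	P3
eastern	p4	1	P4
eastern	p6	1	P6
central	p5	1	P5
central	p6	4	P6
central	p7	1	P7
central	p8	1	P8
western	p9	12	P9
western	p10	1	P10
western	W2	1	W2
western	W3a	2	W3a
western	W3b	2	W3b
western	W4	1	W4
western	W5	3	W5
western	W6	12	W6
western	W7	1	W7
western	W8	2	W8
western	W9a	1	W9a
western	W9b	1	W9b
western	W10	1	W10
western	W11a	1	W11ab
western	W11b	7	W11ab
western	W11c	4	W11c
bonobo	p11	8	P1
bonobo	p12	2	P12
bonobo	B1	2	B1
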