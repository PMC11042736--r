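chrS	100	400	cds001	0	+	CDS	.	.
chrS	460	760	cds002	0	+	CDS	.	.
chrS	820	1120	cds003	0	+	CDS	.	.
chrS	1180	1480	cds004	0	+	CDS	.	.
chrS	1540	1940	rrsX	0	+	rRNA	.	.
chrS	2000	2076	lysT	0	+	tRNA	33	TTT
chrS	2136	2212	gluT	0	-	tRNA	33	TTC
chrS	2272	2348	glnT	0	+	tRNA	33	TTG
chrS	2408	2484	thrT	0	-	tRNA	33	TGT
chrS	2544	2620	asnT	0	+	tRNA	33	GTT
chrS	2680	2756	metT	0	-	tRNA	33	CAT
chrS	2816	2892	lysU	0	+	tRNA	33	TTT
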