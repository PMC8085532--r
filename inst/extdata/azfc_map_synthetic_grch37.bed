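# AZFc amplicon reference map, GRCh37/hg19 chrY.
# Synthetic coordinates: segment order, family copy counts, orientations and
# NAHR span lengths (b2->b4 start-to-start 3.5 Mb, b1->b3 1.6 Mb) follow the
# published AZFc architecture; exact breakpoints are schematic.
# Columns: chrom, start (0-based), end (half-open), id, family, strand.
# scale=1
chrY	14500000	15500000	norm1Mb	norm	+
chrY	23000000	23450000	Gr1	Gr	+
chrY	23450000	23560000	b1	b	+
chrY	23560000	23840000	t1	t	+
chrY	23840000	24000000	P3_spacer	spacer	+
chrY	24000000	24280000	t2	t	-
chrY	24280000	24390000	b2	b	-
chrY	24390000	24450000	IR1	unique	+
chrY	24450000	24570000	g1	g	+
chrY	24570000	24810000	r1	r	+
chrY	24810000	25050000	r2	r	+
chrY	25050000	25160000	b3	b	+
chrY	25160000	26110000	y1	y	+
chrY	26110000	26230000	g2	g	+
chrY	26230000	26470000	r3	r	+
chrY	26470000	26710000	r4	r	+
chrY	26710000	26830000	g3	g	+
chrY	26830000	27780000	y2	y	-
chrY	27780000	27890000	b4	b	-
chrY	27890000	28340000	Gr2	Gr	-
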