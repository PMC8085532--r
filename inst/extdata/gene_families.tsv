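gene_family	host_family	copies_per_segment	external_copies
PRY	b	1	0
RBMY	t	1	4
BPY	g	1	0
DAZ	r	1	0
CDY	y	1	0
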