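Token	POS	Chunk
People	NNS	B-NP
of	IN	B-PP
any	DT	B-NP
age	NN	I-NP
who	WP	B-NP
are	VBP	B-VP
African	JJ	B-NP
Americans	NNP	I-NP
should	MD	B-VP
further	RBR	I-VP
reduce	VB	I-VP
sodium	NN	B-NP
intake	NN	I-NP
to	TO	B-PP
300	CD	B-NP
mg	NN	I-NP
per	IN	B-PP
day	NN	B-NP
.	.	O
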