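# Default-chunking annotation of the total-fiber recommendation sentence.
# Chunk column as produced by the maximum-entropy chunker; POS column is a
# synthetic hand assignment of standard Penn tags (the chunking rules for this
# sentence do not depend on it: it contains no wh-pronoun).
Token	POS	Chunk
The	DT	B-NP
recommended	VBN	I-NP
intake	NN	I-NP
for	IN	B-PP
total	JJ	B-NP
fiber	NN	I-NP
for	IN	B-PP
adults	NNS	B-NP
50	CD	B-NP
years	NNS	I-NP
and	CC	O
younger	JJR	B-NP
is	VBZ	B-VP
set	VBN	I-VP
at	IN	B-PP
38	CD	B-NP
g	NN	I-NP
for	IN	B-PP
men	NNS	B-NP
and	CC	O
25	CD	B-NP
g	NN	I-NP
for	IN	B-PP
women	NNS	B-NP
,	,	O
while	IN	B-ADVP
for	IN	B-PP
men	NNS	B-NP
and	CC	I-NP
women	NNS	I-NP
over	IN	B-PP
50	CD	B-NP
it	PRP	B-NP
is	VBZ	B-VP
30	CD	B-NP
g	NN	I-NP
and	CC	O
21	CD	B-NP
g	NN	I-NP
per	IN	B-PP
day	NN	B-NP
,	,	O
respectively	RB	B-ADVP
,	,	O
due	IN	B-PP
to	TO	I-PP
decreased	VBN	B-NP
food	NN	I-NP
consumptions	NNS	I-NP
.	.	O
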