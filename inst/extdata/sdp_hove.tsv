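# Specificity-determining positions (SDP); positions are reference
# coordinates of the class annotation. Expected residue sets are
# reconstructed from the published match/near-miss verdicts (the table's
# mismatch highlighting is not machine-readable); alternatives '|'.
# TIP boric_acid/co2 and all ammonia SDPs are intentionally not defined.
source	type	class	substrate	position	expected
hove	sdp	PIP	boric_acid	108	T
hove	sdp	PIP	boric_acid	111	I
hove	sdp	PIP	boric_acid	115	H
hove	sdp	PIP	boric_acid	146	A
hove	sdp	PIP	boric_acid	214	I
hove	sdp	PIP	boric_acid	254	K|E|A|D
hove	sdp	PIP	boric_acid	257	W
hove	sdp	PIP	boric_acid	259	D|H
hove	sdp	PIP	boric_acid	261	W
hove	sdp	PIP	co2	136	V
hove	sdp	PIP	co2	139	I
hove	sdp	PIP	co2	143	S
hove	sdp	PIP	co2	156	F
hove	sdp	PIP	co2	220	I
hove	sdp	PIP	co2	260	H
hove	sdp	PIP	co2	263	F
hove	sdp	PIP	co2	265	M
hove	sdp	PIP	co2	267	P
hove	sdp	PIP	h2o2	125	F
hove	sdp	PIP	h2o2	146	A
hove	sdp	PIP	h2o2	149	G
hove	sdp	PIP	h2o2	153	V
hove	sdp	PIP	h2o2	193	L
hove	sdp	PIP	h2o2	233	P
hove	sdp	PIP	h2o2	236	G
hove	sdp	PIP	h2o2	238	G
hove	sdp	PIP	h2o2	265	V
hove	sdp	PIP	urea	115	H
hove	sdp	PIP	urea	118	P
hove	sdp	PIP	urea	122	F
hove	sdp	PIP	urea	186	E
hove	sdp	PIP	urea	226	L|M
hove	sdp	PIP	urea	229	L
hove	sdp	PIP	urea	231	T
hove	sdp	PIP	urea	233	P
hove	sdp	PIP	urea	240	N
hove	sdp	TIP	h2o2	116	A|S
hove	sdp	TIP	h2o2	119	A
hove	sdp	TIP	h2o2	123	L
hove	sdp	TIP	h2o2	126	F
hove	sdp	TIP	h2o2	182	I
hove	sdp	TIP	h2o2	219	H|N
hove	sdp	TIP	h2o2	222	Y
hove	sdp	TIP	h2o2	224	L|V
hove	sdp	TIP	h2o2	226	P
hove	sdp	TIP	urea	85	H
hove	sdp	TIP	urea	88	P
hove	sdp	TIP	urea	92	F
hove	sdp	TIP	urea	95	L|A
hove	sdp	TIP	urea	158	L
hove	sdp	TIP	urea	195	P
hove	sdp	TIP	urea	198	G
hove	sdp	TIP	urea	200	S
hove	sdp	TIP	urea	202	N
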