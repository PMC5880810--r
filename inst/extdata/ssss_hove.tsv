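# Substrate-specific signature sequences (SSSS).
# Positions: B1..B10 loop-B NPA window, E1..E11 loop-E NPA window,
# H2/H5/LE1/LE2 Ar/R filter, P1..P5 Froger positions.
# expected lists allowed residues, alternatives separated by '|'.
# A (class, substrate) pair with no rows is not defined for this source.
source	type	class	substrate	position	expected
hove	ssss	PIP	h2o2	B1	S
hove	ssss	PIP	h2o2	B2	G
hove	ssss	PIP	h2o2	B3	G
hove	ssss	PIP	h2o2	B4	H
hove	ssss	PIP	h2o2	B5	I
hove	ssss	PIP	h2o2	B6	N
hove	ssss	PIP	h2o2	B7	P
hove	ssss	PIP	h2o2	B8	A
hove	ssss	PIP	h2o2	B9	V
hove	ssss	PIP	h2o2	B10	T
hove	ssss	PIP	h2o2	E1	G
hove	ssss	PIP	h2o2	E2	T
hove	ssss	PIP	h2o2	E3	G
hove	ssss	PIP	h2o2	E4	I
hove	ssss	PIP	h2o2	E5	N
hove	ssss	PIP	h2o2	E6	P
hove	ssss	PIP	h2o2	E7	A
hove	ssss	PIP	h2o2	E8	R
hove	ssss	PIP	h2o2	E9	S
hove	ssss	PIP	h2o2	E10	L|F
hove	ssss	PIP	h2o2	E11	G
hove	ssss	PIP	h2o2	H2	F
hove	ssss	PIP	h2o2	H5	H
hove	ssss	PIP	h2o2	LE1	T
hove	ssss	PIP	h2o2	LE2	R
hove	ssss	PIP	h2o2	P1	Q
hove	ssss	PIP	h2o2	P2	S
hove	ssss	PIP	h2o2	P3	A
hove	ssss	PIP	h2o2	P4	F
hove	ssss	PIP	h2o2	P5	W
hove	ssss	PIP	urea	B1	S
hove	ssss	PIP	urea	B2	G
hove	ssss	PIP	urea	B3	G
hove	ssss	PIP	urea	B4	H
hove	ssss	PIP	urea	B5	I
hove	ssss	PIP	urea	B6	N
hove	ssss	PIP	urea	B7	P
hove	ssss	PIP	urea	B8	A
hove	ssss	PIP	urea	B9	V
hove	ssss	PIP	urea	B10	T
hove	ssss	PIP	urea	E1	G
hove	ssss	PIP	urea	E2	T
hove	ssss	PIP	urea	E3	G
hove	ssss	PIP	urea	E4	I
hove	ssss	PIP	urea	E5	N
hove	ssss	PIP	urea	E6	P
hove	ssss	PIP	urea	E7	A
hove	ssss	PIP	urea	E8	R
hove	ssss	PIP	urea	E9	S
hove	ssss	PIP	urea	E10	L|F
hove	ssss	PIP	urea	E11	G
hove	ssss	PIP	urea	H2	F
hove	ssss	PIP	urea	H5	H
hove	ssss	PIP	urea	LE1	T
hove	ssss	PIP	urea	LE2	R
hove	ssss	PIP	urea	P1	Q
hove	ssss	PIP	urea	P2	S
hove	ssss	PIP	urea	P3	A
hove	ssss	PIP	urea	P4	F
hove	ssss	PIP	urea	P5	W
hove	ssss	PIP	boric_acid	B1	S
hove	ssss	PIP	boric_acid	B2	G
hove	ssss	PIP	boric_acid	B3	G
hove	ssss	PIP	boric_acid	B4	H
hove	ssss	PIP	boric_acid	B5	I
hove	ssss	PIP	boric_acid	B6	N
hove	ssss	PIP	boric_acid	B7	P
hove	ssss	PIP	boric_acid	B8	A
hove	ssss	PIP	boric_acid	B9	V
hove	ssss	PIP	boric_acid	B10	T
hove	ssss	PIP	boric_acid	E1	G
hove	ssss	PIP	boric_acid	E2	T
hove	ssss	PIP	boric_acid	E3	G
hove	ssss	PIP	boric_acid	E4	I
hove	ssss	PIP	boric_acid	E5	N
hove	ssss	PIP	boric_acid	E6	P
hove	ssss	PIP	boric_acid	E7	A
hove	ssss	PIP	boric_acid	E8	R
hove	ssss	PIP	boric_acid	E9	S
hove	ssss	PIP	boric_acid	E10	L
hove	ssss	PIP	boric_acid	E11	G
hove	ssss	PIP	boric_acid	H2	F
hove	ssss	PIP	boric_acid	H5	H
hove	ssss	PIP	boric_acid	LE1	T
hove	ssss	PIP	boric_acid	LE2	R
hove	ssss	PIP	boric_acid	P1	Q
hove	ssss	PIP	boric_acid	P2	S
hove	ssss	PIP	boric_acid	P3	A
hove	ssss	PIP	boric_acid	P4	F
hove	ssss	PIP	boric_acid	P5	W
hove	ssss	PIP	co2	B1	S
hove	ssss	PIP	co2	B2	G
hove	ssss	PIP	co2	B3	G
hove	ssss	PIP	co2	B4	H
hove	ssss	PIP	co2	B5	I
hove	ssss	PIP	co2	B6	N
hove	ssss	PIP	co2	B7	P
hove	ssss	PIP	co2	B8	A
hove	ssss	PIP	co2	B9	V
hove	ssss	PIP	co2	B10	T
hove	ssss	PIP	co2	E1	G
hove	ssss	PIP	co2	E2	T
hove	ssss	PIP	co2	E3	G
hove	ssss	PIP	co2	E4	I
hove	ssss	PIP	co2	E5	N
hove	ssss	PIP	co2	E6	P
hove	ssss	PIP	co2	E7	A
hove	ssss	PIP	co2	E8	R
hove	ssss	PIP	co2	E9	S
hove	ssss	PIP	co2	E10	L
hove	ssss	PIP	co2	E11	G
hove	ssss	PIP	co2	H2	F
hove	ssss	PIP	co2	H5	H
hove	ssss	PIP	co2	LE1	T
hove	ssss	PIP	co2	LE2	R
hove	ssss	PIP	co2	P1	Q
hove	ssss	PIP	co2	P2	S
hove	ssss	PIP	co2	P3	A
hove	ssss	PIP	co2	P4	F
hove	ssss	PIP	co2	P5	W
hove	ssss	TIP	h2o2	B1	S
hove	ssss	TIP	h2o2	B2	G
hove	ssss	TIP	h2o2	B3	G
hove	ssss	TIP	h2o2	B4	H
hove	ssss	TIP	h2o2	B5	V|L
hove	ssss	TIP	h2o2	B6	N
hove	ssss	TIP	h2o2	B7	P
hove	ssss	TIP	h2o2	B8	A
hove	ssss	TIP	h2o2	B9	V
hove	ssss	TIP	h2o2	B10	T
hove	ssss	TIP	h2o2	E1	G
hove	ssss	TIP	h2o2	E2	A|G
hove	ssss	TIP	h2o2	E3	S
hove	ssss	TIP	h2o2	E4	M
hove	ssss	TIP	h2o2	E5	N
hove	ssss	TIP	h2o2	E6	P
hove	ssss	TIP	h2o2	E7	A
hove	ssss	TIP	h2o2	E8	R
hove	ssss	TIP	h2o2	E9	A|S
hove	ssss	TIP	h2o2	E10	F
hove	ssss	TIP	h2o2	E11	G
hove	ssss	TIP	h2o2	H2	H
hove	ssss	TIP	h2o2	H5	I
hove	ssss	TIP	h2o2	LE1	A|G
hove	ssss	TIP	h2o2	LE2	R
hove	ssss	TIP	h2o2	P1	T
hove	ssss	TIP	h2o2	P2	A|S
hove	ssss	TIP	h2o2	P3	A
hove	ssss	TIP	h2o2	P4	Y
hove	ssss	TIP	h2o2	P5	W
hove	ssss	TIP	urea	B1	S
hove	ssss	TIP	urea	B2	G
hove	ssss	TIP	urea	B3	G
hove	ssss	TIP	urea	B4	H
hove	ssss	TIP	urea	B5	V|L
hove	ssss	TIP	urea	B6	N
hove	ssss	TIP	urea	B7	P
hove	ssss	TIP	urea	B8	A
hove	ssss	TIP	urea	B9	V
hove	ssss	TIP	urea	B10	T
hove	ssss	TIP	urea	E1	G
hove	ssss	TIP	urea	E2	A|G
hove	ssss	TIP	urea	E3	S
hove	ssss	TIP	urea	E4	M
hove	ssss	TIP	urea	E5	N
hove	ssss	TIP	urea	E6	P
hove	ssss	TIP	urea	E7	A
hove	ssss	TIP	urea	E8	R
hove	ssss	TIP	urea	E9	A|S
hove	ssss	TIP	urea	E10	F
hove	ssss	TIP	urea	E11	G
hove	ssss	TIP	urea	H2	H
hove	ssss	TIP	urea	H5	I
hove	ssss	TIP	urea	LE1	A|G
hove	ssss	TIP	urea	LE2	R
hove	ssss	TIP	urea	P1	T
hove	ssss	TIP	urea	P2	A|S
hove	ssss	TIP	urea	P3	A
hove	ssss	TIP	urea	P4	Y
hove	ssss	TIP	urea	P5	W
hove	ssss	TIP	ammonia	B1	S
hove	ssss	TIP	ammonia	B2	G
hove	ssss	TIP	ammonia	B3	G
hove	ssss	TIP	ammonia	B4	H
hove	ssss	TIP	ammonia	B5	L
hove	ssss	TIP	ammonia	B6	N
hove	ssss	TIP	ammonia	B7	P
hove	ssss	TIP	ammonia	B8	A
hove	ssss	TIP	ammonia	B9	V
hove	ssss	TIP	ammonia	B10	T
hove	ssss	TIP	ammonia	E1	G
hove	ssss	TIP	ammonia	E2	G
hove	ssss	TIP	ammonia	E3	S
hove	ssss	TIP	ammonia	E4	M
hove	ssss	TIP	ammonia	E5	N
hove	ssss	TIP	ammonia	E6	P
hove	ssss	TIP	ammonia	E7	A
hove	ssss	TIP	ammonia	E8	R
hove	ssss	TIP	ammonia	E9	S
hove	ssss	TIP	ammonia	E10	F
hove	ssss	TIP	ammonia	E11	G
hove	ssss	TIP	ammonia	H2	H
hove	ssss	TIP	ammonia	H5	I
hove	ssss	TIP	ammonia	LE1	G
hove	ssss	TIP	ammonia	LE2	R
hove	ssss	TIP	ammonia	P1	T
hove	ssss	TIP	ammonia	P2	S
hove	ssss	TIP	ammonia	P3	A
hove	ssss	TIP	ammonia	P4	Y
hove	ssss	TIP	ammonia	P5	W
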