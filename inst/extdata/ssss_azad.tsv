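# Substrate-specific signature sequences (SSSS).
# Positions: B1..B10 loop-B NPA window, E1..E11 loop-E NPA window,
# H2/H5/LE1/LE2 Ar/R filter, P1..P5 Froger positions.
# expected lists allowed residues, alternatives separated by '|'.
# A (class, substrate) pair with no rows is not defined for this source.
source	type	class	substrate	position	expected
azad	ssss	PIP	h2o2	B1	S
azad	ssss	PIP	h2o2	B2	G
azad	ssss	PIP	h2o2	B3	G
azad	ssss	PIP	h2o2	B4	H
azad	ssss	PIP	h2o2	B5	I
azad	ssss	PIP	h2o2	B6	N
azad	ssss	PIP	h2o2	B7	P
azad	ssss	PIP	h2o2	B8	A
azad	ssss	PIP	h2o2	B9	V
azad	ssss	PIP	h2o2	B10	T
azad	ssss	PIP	h2o2	E1	G
azad	ssss	PIP	h2o2	E2	T
azad	ssss	PIP	h2o2	E3	G
azad	ssss	PIP	h2o2	E4	I
azad	ssss	PIP	h2o2	E5	N
azad	ssss	PIP	h2o2	E6	P
azad	ssss	PIP	h2o2	E7	A
azad	ssss	PIP	h2o2	E8	R
azad	ssss	PIP	h2o2	E9	S
azad	ssss	PIP	h2o2	E10	L|F
azad	ssss	PIP	h2o2	E11	G
azad	ssss	PIP	h2o2	H2	F
azad	ssss	PIP	h2o2	H5	H
azad	ssss	PIP	h2o2	LE1	T
azad	ssss	PIP	h2o2	LE2	R
azad	ssss	PIP	h2o2	P1	Q
azad	ssss	PIP	h2o2	P2	S
azad	ssss	PIP	h2o2	P3	A
azad	ssss	PIP	h2o2	P4	F
azad	ssss	PIP	h2o2	P5	W
azad	ssss	PIP	co2	B1	S
azad	ssss	PIP	co2	B2	G
azad	ssss	PIP	co2	B3	G
azad	ssss	PIP	co2	B4	H
azad	ssss	PIP	co2	B5	I
azad	ssss	PIP	co2	B6	N
azad	ssss	PIP	co2	B7	P
azad	ssss	PIP	co2	B8	A
azad	ssss	PIP	co2	B9	V
azad	ssss	PIP	co2	B10	T
azad	ssss	PIP	co2	E1	G
azad	ssss	PIP	co2	E2	T
azad	ssss	PIP	co2	E3	G
azad	ssss	PIP	co2	E4	I
azad	ssss	PIP	co2	E5	N
azad	ssss	PIP	co2	E6	P
azad	ssss	PIP	co2	E7	A
azad	ssss	PIP	co2	E8	R
azad	ssss	PIP	co2	E9	S
azad	ssss	PIP	co2	E10	L
azad	ssss	PIP	co2	E11	G
azad	ssss	PIP	co2	H2	F
azad	ssss	PIP	co2	H5	H
azad	ssss	PIP	co2	LE1	T
azad	ssss	PIP	co2	LE2	R
azad	ssss	PIP	co2	P1	Q
azad	ssss	PIP	co2	P2	S
azad	ssss	PIP	co2	P3	A
azad	ssss	PIP	co2	P4	F
azad	ssss	PIP	co2	P5	W
azad	ssss	TIP	h2o2	B1	S
azad	ssss	TIP	h2o2	B2	G
azad	ssss	TIP	h2o2	B3	G
azad	ssss	TIP	h2o2	B4	H
azad	ssss	TIP	h2o2	B5	L
azad	ssss	TIP	h2o2	B6	N
azad	ssss	TIP	h2o2	B7	P
azad	ssss	TIP	h2o2	B8	A
azad	ssss	TIP	h2o2	B9	V
azad	ssss	TIP	h2o2	B10	T
azad	ssss	TIP	h2o2	E1	G
azad	ssss	TIP	h2o2	E2	G
azad	ssss	TIP	h2o2	E3	S
azad	ssss	TIP	h2o2	E4	M
azad	ssss	TIP	h2o2	E5	N
azad	ssss	TIP	h2o2	E6	P
azad	ssss	TIP	h2o2	E7	A
azad	ssss	TIP	h2o2	E8	R
azad	ssss	TIP	h2o2	E9	S
azad	ssss	TIP	h2o2	E10	F
azad	ssss	TIP	h2o2	E11	G
azad	ssss	TIP	h2o2	H2	H
azad	ssss	TIP	h2o2	H5	I
azad	ssss	TIP	h2o2	LE1	G
azad	ssss	TIP	h2o2	LE2	R
azad	ssss	TIP	h2o2	P1	T
azad	ssss	TIP	h2o2	P2	S
azad	ssss	TIP	h2o2	P3	A
azad	ssss	TIP	h2o2	P4	Y
azad	ssss	TIP	h2o2	P5	W
azad	ssss	TIP	urea	B1	S
azad	ssss	TIP	urea	B2	G
azad	ssss	TIP	urea	B3	G
azad	ssss	TIP	urea	B4	H
azad	ssss	TIP	urea	B5	L
azad	ssss	TIP	urea	B6	N
azad	ssss	TIP	urea	B7	P
azad	ssss	TIP	urea	B8	A
azad	ssss	TIP	urea	B9	V
azad	ssss	TIP	urea	B10	T
azad	ssss	TIP	urea	E1	G
azad	ssss	TIP	urea	E2	G
azad	ssss	TIP	urea	E3	S
azad	ssss	TIP	urea	E4	M
azad	ssss	TIP	urea	E5	N
azad	ssss	TIP	urea	E6	P
azad	ssss	TIP	urea	E7	A
azad	ssss	TIP	urea	E8	R
azad	ssss	TIP	urea	E9	S
azad	ssss	TIP	urea	E10	F
azad	ssss	TIP	urea	E11	G
azad	ssss	TIP	urea	H2	H
azad	ssss	TIP	urea	H5	I
azad	ssss	TIP	urea	LE1	G
azad	ssss	TIP	urea	LE2	R
azad	ssss	TIP	urea	P1	T
azad	ssss	TIP	urea	P2	S
azad	ssss	TIP	urea	P3	A
azad	ssss	TIP	urea	P4	Y
azad	ssss	TIP	urea	P5	W
azad	ssss	TIP	ammonia	B1	S
azad	ssss	TIP	ammonia	B2	G
azad	ssss	TIP	ammonia	B3	G
azad	ssss	TIP	ammonia	B4	H
azad	ssss	TIP	ammonia	B5	L
azad	ssss	TIP	ammonia	B6	N
azad	ssss	TIP	ammonia	B7	P
azad	ssss	TIP	ammonia	B8	A
azad	ssss	TIP	ammonia	B9	V
azad	ssss	TIP	ammonia	B10	T
azad	ssss	TIP	ammonia	E1	G
azad	ssss	TIP	ammonia	E2	G
azad	ssss	TIP	ammonia	E3	S
azad	ssss	TIP	ammonia	E4	M
azad	ssss	TIP	ammonia	E5	N
azad	ssss	TIP	ammonia	E6	P
azad	ssss	TIP	ammonia	E7	A
azad	ssss	TIP	ammonia	E8	R
azad	ssss	TIP	ammonia	E9	S
azad	ssss	TIP	ammonia	E10	F
azad	ssss	TIP	ammonia	E11	G
azad	ssss	TIP	ammonia	H2	H
azad	ssss	TIP	ammonia	H5	I
azad	ssss	TIP	ammonia	LE1	G
azad	ssss	TIP	ammonia	LE2	R
azad	ssss	TIP	ammonia	P1	T
azad	ssss	TIP	ammonia	P2	S
azad	ssss	TIP	ammonia	P3	A
azad	ssss	TIP	ammonia	P4	Y
azad	ssss	TIP	ammonia	P5	W
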