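# Synthetic PIP reference annotation.
# Coordinates are 1-based and inclusive, matching the numbering of the
# published PIP alignment figure (positions 103/249 = permeability pair,
# SDP coordinates 108..267, NPA motifs at 117-119 and 240-242).
# The reference sequence is a synthetic six-helix scaffold carrying the
# published signature residues; substitute your own annotated reference
# FASTA (e.g. a real accession translation) via sequence_file to re-anchor.

[meta]
reference_id = FaPIP_ref_synthetic
class = PIP
sequence_file = pip_reference_synthetic.fasta

[npa]
loopB_start = 112
loopB_len = 10
loopE_start = 236
loopE_len = 11

[arr]
H2 = 95
H5 = 222
LE1 = 237
LE2 = 243

[froger]
P1 = 199
P2 = 250
P3 = 251
P4 = 263
P5 = 264

[positions]
loopD = 205
perm_TM2 = 103
perm_loopE = 249

[gating]
loopB_S = 112 S
cterm_S = 287 S
loopD_H = 203 H
loopD_L = 205 L
meth_K = 4 K
meth_E = 6 E

[sdp]
boric_acid = 108 111 115 146 214 254 257 259 261
co2 = 136 139 143 156 220 260 263 265 267
h2o2 = 125 146 149 153 193 233 236 238 265
urea = 115 118 122 186 226 229 231 233 240
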