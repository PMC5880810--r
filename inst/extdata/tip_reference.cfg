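# Synthetic TIP reference annotation.
# Coordinates are 1-based and inclusive, matching the numbering of the
# published TIP alignment figure (SDP coordinates 85..226, NPA motifs at
# 87-89 and 202-204). The reference sequence is a synthetic six-helix
# scaffold; substitute a real annotated reference via sequence_file.

[meta]
reference_id = FaTIP_ref_synthetic
class = TIP
sequence_file = tip_reference_synthetic.fasta

[npa]
loopB_start = 82
loopB_len = 10
loopE_start = 198
loopE_len = 11

[arr]
H2 = 65
H5 = 185
LE1 = 199
LE2 = 205

[froger]
P1 = 150
P2 = 206
P3 = 210
P4 = 222
P5 = 223

[positions]
loopD = 175
perm_TM2 = 68
perm_loopE = 212

[gating]
loopB_T = 91 T

[sdp]
h2o2 = 116 119 123 126 182 219 222 224 226
urea = 85 88 92 95 158 195 198 200 202
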