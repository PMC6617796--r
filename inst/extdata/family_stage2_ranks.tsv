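# Published genome-wide Stage-2 (H_max) ranks of the known pathogenic
# variant for the breast-cancer family: three carriers (C) and three
# noncarriers (N).
id	stage2Rank	label
S1	268	C
S5	480	C
S9	468	C
S2	366	N
S6	994	N
S7	587	N
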