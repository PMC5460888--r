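variant_id	dose_uM	replicate	cells_plated	resistant_colonies
CTRL	0	1	1500000	1
CTRL	0	2	1500000	2
CTRL	4	1	1500000	2
CTRL	4	2	1500000	3
V397E	0	1	1500000	28
V397E	0	2	1500000	35
V397E	4	1	1500000	310
V397E	4	2	1500000	285
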