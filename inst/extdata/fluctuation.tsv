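variant_id	replicate	n_expanded	cells_per_plate	n_plates	geneticin_total
CTRL	1	1e+07	1e+05	100	7
CTRL	2	1e+07	1e+05	100	9
CTRL	3	1e+07	1e+05	100	8
CTRL	4	1e+07	1e+05	100	10
V397E	1	1e+07	1e+05	100	23000
V397E	2	1e+07	1e+05	100	25500
V397E	3	1e+07	1e+05	100	21800
V397E	4	1e+07	1e+05	100	26400
UNIT	1	1e+07	1e+05	100	4.53046971409841
ZERO	1	1e+07	1e+05	100	0
ZERO	2	1e+07	1e+05	100	0
ZERO	3	1e+07	1e+05	100	0
ZERO	4	1e+07	1e+05	100	0
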