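peptide	sequence	modification_type	modification	t_half_hours
PTH25-37	RKKLQDVHNFVAL			
P1	RKKLQD-Azo-VHNFVAL	i	D30-Azo-V31	90
P2	RKKLQDV-Azo-HNFVAL	i	V31-Azo-H32	90
P3	RKKLQ-Azo-VHNFVAL	e	D30 -> Azo	
P4	RKKLQD-Azo-HNFVAL	e	V31 -> Azo	97
P5	RKKLQ-Azo-HNFVAL	e	D30,V31 -> Azo	
P6	RKKLQ-Azo-DVHNFVAL	i	Q29-Azo-D30	
P7	RKKL-Azo-QDVHNFVAL	i	L28-Azo-Q29	72
P8	RK-Azo-KLQDVHNFVAL	i	K26-Azo-K27	89
P9	R-Azo-KLQDVHNFVAL	e	K26 -> Azo	86
P10	RKKLQDVHN-Azo-FVAL	i	N33-Azo-F34	
P11	RKKLQDVHNFV-Azo-AL	i	V35-Azo-A36	
P12	RKKLQDVHNF-Azo-AL	e	V35 -> Azo	63
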