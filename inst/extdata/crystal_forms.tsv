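form	accession	pH	space_group	a	b	c	alpha	beta	gamma	z_prime
apo_pH5	7FHX	5.0	P 21 21 21	49.131	94.737	160.499	90	90	90	2
apo_pH7	7FHY	7.0	P 1	43.652	57.943	67.569	71.14	89.71	73.79	2
apo_pH9	7FHZ	9.0	P 21 21 2	47.983	160.579	46.942	90	90	90	1
manA_pH5	7FI0	5.0	C 2 2 21	105.757	160.662	48.160	90	90	90	1
manA_pH7	7FI1	7.0	P 21 21 2	48.139	160.228	46.878	90	90	90	1
ha_pH5	7FI2	5.0	P 31 2 1	75.564	75.564	112.360	90	90	120	1
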