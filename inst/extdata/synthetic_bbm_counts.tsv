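# synthetic stand-in spectral-count table (NOT measured data)
# group ratios for Vil1, Baiap2l1, Ush1c, Actb constructed from published fold changes
protein_id	gene_symbol	control_vehicle	control_glp2	ko_vehicle	ko_glp2
P86W56	Vil1	300	429	300	300
Q9DBJ3	Baiap2l1	100	100	239	138
Q9ES64	Ush1c	100	100	385	169
P60710	Actb	800	800	1652	944
Q9WTI7	Myo1a	400	408	396	404
P17742	Ezr	210	224	205	218
Q3V0K9	Pls1	180	176	184	179
Q61086	Espn	95	99	104	98
Q8VDD5	Myh9	310	302	315	308
Q80X90	Flnb	120	118	125	121
P16858	Gapdh	520	530	515	525
Q91Y97	Aldob	610	598	605	612
P17182	Eno1	330	340	328	334
P14094	Atp1b1	150	149	154	151
P09803	Cdh1	88	91	86	90
Q8K1F1	Sis	260	272	255	265
P97449	Anpep	240	236	242	238
Q9Z0S1	Slc5a1	130	134	128	131
P63017	Hspa8	410	402	415	409
P24822	Alpi	190	197	186	193
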