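name	WA	WB	mature_seq	arm	size	lp	mfe	location
rsa-miRn3	443	0	TATTCCGACGACAATTCCGACG	5'	22	100	-56.31	CL2831.Contig4,Contig6
rsa-miRn3*	8	0	TCGGAATTCCGTCGGAATATA	3'	21	100	-56.31	CL2831.Contig4,Contig6
rsa-miRn4	519	637	AATGTATGTAGTCCAATCTAT	5'	21	117	-66	CL2870.Contig2
rsa-miRn4*	18	6	ACATTGGACTACATATATTAC	3'	21	117	-66	CL2870.Contig2
rsa-miRn5	1141	1452	GCTTCCATATCTAGCAGTAGG	5'	21	184	-75.8	CL2916.Contig2
rsa-miRn5*	6	12	TACCGATAGATGTGGAAGCGT	3'	21	184	-75.8	CL2916.Contig2
rsa-miRn7	21141	24827	TTTGCGTGAGTATGTGGATGT	5'	21	119	-49	CL4600.Contig2
rsa-miRn7*	32	42	ATCCACATACTCACGAAAATC	3'	21	119	-49	CL4600.Contig2
rsa-miRn9a	771	1062	CGTTCAGTTCTCCTTTTGCTTC	5'	22	106	-47.24	Rsa#S43006900
rsa-miRn9a*	7	28	AGCAAACGAGAATTGAACGGA	3'	21	106	-47.24	Rsa#S43006900
rsa-miRn19	0	186	GAACGATATAAAAGATCATGGA	5'	22	105	-30.2	CL6156.Contig1,Contig2
rsa-miRn19*	0	44	TATGGCCTTTATATCGTATTCG	3'	22	105	-30.2	CL6156.Contig1,Contig2
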