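family	members	conserved	WA	WB
miR156/157	14	yes	410237	304695
miR158	2	yes	15565	7641
miR159	4	yes	1726	1157
miR160	6	yes	13463	18893
miR161	1	yes	152	0
miR162	3	yes	1211	1379
miR164	5	yes	9831	9100
miR165/166	17	yes	321161	405255
miR167	8	yes	318811	276963
miR168	3	yes	137677	135624
miR169	11	yes	36871	37179
miR171	6	yes	3241	4824
miR172	7	yes	9866	13246
miR319	4	yes	508	976
miR390	5	yes	7594	10560
miR391	2	yes	3769	3177
miR393	3	yes	1789	1643
miR394	3	yes	358	348
miR395	2	yes	45236	44
miR396	6	yes	3751	2853
miR397	1	yes	13	60
miR398	2	yes	223	285
miR399	3	yes	108	80
miR403	2	yes	1455	1306
miR408	4	yes	3431	7780
miR400	2	no	43	33
miR447	1	no	189	245
miR482	2	no	2073	35
miR529	3	no	68	55
miR535	2	no	2229	83
miR824	2	no	651	681
miR825	1	no	354	479
miR827	3	no	1932	2558
miR828	1	no	5	71
miR829	1	no	36	98
miR831	1	no	87	58
miR845	3	no	5094	5262
miR854	1	no	640	468
miR858	1	no	0	26
miR859	1	no	671	0
miR860	1	no	248	215
miR948	1	no	0	336
miR1878	1	no	0	1584
miR1885	2	no	1961	4902
miR2111	4	no	91	206
miR2118	1	no	42998	60406
miR2199	1	no	42085	44471
miR3444	1	no	0	452
miR5654	1	no	1298	1705
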