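gene	start	end	size	strand	direction	intergenic	codons
trnI	1	64	64	N	forward	0
trnQ	62	130	69	J	reverse	-3
trnM	131	201	71	N	forward	0
nad2	202	1188	987	N	forward	0	ATT/TAA
trnW	1179	1242	64	N	forward	-10
trnC	1235	1297	63	J	reverse	-8
trnY	1305	1373	69	J	reverse	10
cox1	1377	2910	1534	N	forward	3	TTG/T-
trnL2	2911	2975	65	N	forward	0
cox2	2976	3651	676	N	forward	0	ATA/T-
trnK	3652	3716	65	N	forward	0
trnD	3717	3777	61	N	forward	0
atp8	3778	3936	159	N	forward	0	ATA/TAA
atp6	3930	4595	666	N	forward	-7	ATG/TAA
cox3	4604	5381	778	N	forward	8	ATT/T-
trnG	5382	5444	63	N	forward	0
nad3	5445	5798	354	N	forward	0	ATA/TAG
trnA	5797	5860	64	N	forward	-2
trnR	5861	5920	60	N	forward	0
trnN	5923	5990	68	N	forward	2
trnS1	5990	6058	69	N	forward	-1
trnE	6058	6121	64	N	forward	-1
trnF	6122	6184	63	J	reverse	0
nad5	6185	7882	1698	J	reverse	0	ATT/TAA
trnH	7886	7949	64	J	reverse	3
nad4	7988	9304	1317	J	reverse	38	ATG/TAA
nad4l	9298	9606	309	J	reverse	-7	TTG/TAA
trnT	9582	9644	63	N	forward	-25
trnP	9645	9707	63	J	reverse	0
nad6	9710	10171	462	N	forward	2	ATC/TAA
cob	10171	11307	1137	N	forward	-1	ATG/TAG
trnS2	11306	11375	70	N	forward	-2
nad1	11397	12320	924	J	reverse	21	ATC/TAA
trnL1	12321	12385	65	J	reverse	0
rrnL	12397	13613	1217	J	reverse	11
trnV	13636	13701	66	J	reverse	22
rrnS	13727	14316	590	J	reverse	25
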