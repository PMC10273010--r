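gene	start	end	size	strand	direction	intergenic	codons
trnI	1	64	64	N	forward	0
trnQ	62	130	69	J	reverse	-3
trnM	131	200	70	N	forward	0
nad2	201	1187	987	N	forward	0	ATT/TAA
trnW	1178	1241	64	N	forward	-10
trnC	1234	1296	63	J	reverse	-8
trnY	1303	1370	68	J	reverse	6
cox1	1374	2907	1534	N	forward	3	TTG/T-
trnL2	2908	2972	65	N	forward	0
cox2	2973	3648	676	N	forward	0	ATA/T-
trnK	3649	3713	65	N	forward	0
trnD	3714	3774	61	N	forward	0
atp8	3775	3933	159	N	forward	0	ATA/TAA
atp6	3927	4592	666	N	forward	-7	ATG/TAA
cox3	4601	5378	778	N	forward	8	ATT/T-
trnG	5379	5443	65	N	forward	0
nad3	5444	5797	354	N	forward	0	ATA/TAG
trnA	5796	5860	65	N	forward	-2
trnR	5861	5920	60	N	forward	0
trnN	5923	5990	68	N	forward	2
trnS1	5990	6058	69	N	forward	-1
trnE	6058	6121	64	N	forward	-1
trnF	6122	6184	63	J	reverse	0
nad5	6185	7882	1698	J	reverse	0	ATT/TAA
trnH	7886	7949	64	J	reverse	3
nad4	7987	9303	1317	J	reverse	37	ATG/TAA
nad4l	9297	9605	309	J	reverse	-7	TTG/TAA
trnT	9581	9643	63	N	forward	-25
trnP	9644	9706	63	J	reverse	0
nad6	9709	10170	462	N	forward	2	ATC/TAA
cob	10170	11306	1137	N	forward	-1	ATG/TAG
trnS2	11305	11374	70	N	forward	-2
nad1	11396	12319	924	J	reverse	21	ATC/TAA
trnL1	12320	12384	65	J	reverse	0
rrnL	12392	13612	1221	J	reverse	7
trnV	13635	13700	66	J	reverse	22
rrnS	13726	14315	590	J	reverse	25
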