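carbons	double_bonds	abbreviation	name
14	0	MA	myristic acid
14	1	NA	myristoleic acid
15	0	NA	pentadecanoic acid
15	1	NA	pentadecenoic acid
16	0	PA	palmitic acid
16	1	POA	palmitoleic acid
17	0	NA	margaric acid
17	1	NA	heptadecenoic acid
18	0	SA	stearic acid
18	1	OA	oleic acid
18	2	LA	linoleic acid
18	3	ALA	alpha-linolenic acid
18	4	NA	stearidonic acid
19	0	NA	nonadecanoic acid
20	0	NA	arachidic acid
20	1	NA	gondoic acid
20	2	NA	eicosadienoic acid
20	3	NA	dihomo-gamma-linolenic acid
20	4	AA	arachidonic acid
20	5	EPA	eicosapentaenoic acid
21	0	NA	heneicosanoic acid
22	0	NA	behenic acid
22	1	NA	erucic acid
22	2	NA	docosadienoic acid
22	4	NA	adrenic acid
22	5	DPA	docosapentaenoic acid
22	6	DHA	docosahexaenoic acid
23	0	NA	tricosanoic acid
24	0	NA	lignoceric acid
24	1	NA	nervonic acid
24	4	NA	tetracosatetraenoic acid
24	5	NA	tetracosapentaenoic acid
24	6	NA	tetracosahexaenoic acid
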