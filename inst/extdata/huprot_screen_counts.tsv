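condition	group	isoform	total	unique	printed_isoform_pct
50X-SUMO1	50X	SUMO1	2346	NA	54.8
50X-SUMO2	50X	SUMO2	1933	NA	45.2
PIAS1-SUMO1	PIAS1	SUMO1	767	184	47.3
PIAS1-SUMO2	PIAS1	SUMO2	853	366	52.7
PIAS2-SUMO1	PIAS2	SUMO1	329	48	NA
PIAS3-SUMO1	PIAS3	SUMO1	70	0	6
PIAS3-SUMO2	PIAS3	SUMO2	1092	470	94
PIAS4-SUMO1	PIAS4	SUMO1	3	0	1
PIAS4-SUMO2	PIAS4	SUMO2	249	26	99
RANBP2-SUMO1	RANBP2	SUMO1	181	33	62.8
RANBP2-SUMO2	RANBP2	SUMO2	99	7	37.2
TOPORS-SUMO1	TOPORS	SUMO1	197	46	73
TOPORS-SUMO2	TOPORS	SUMO2	73	2	27
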