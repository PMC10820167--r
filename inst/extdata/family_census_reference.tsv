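species	total	oneR	twoR	threeR	fourR	fiveR
Arabidopsis thaliana	272	138	128	5	1	0
Vitis vinifera	269	135	128	6	0	0
Triticum aestivum	608	357	237	11	3	0
Oryza sativa	258	144	108	5	0	1
Setaria italica	285	157	122	4	2	0
Solanum lycopersicum	293	161	127	4	1	0
Solanum tuberosum	330	187	138	4	1	0
Nicotiana tabacum	536	326	197	11	2	0
Glycine max	610	306	294	8	2	0
Arachis hypogaea	541	292	238	9	2	0
Medicago truncatula	355	188	161	5	1	0
Linum usitatissimum	434	235	194	3	1	1
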