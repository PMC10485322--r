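# synthetic stand-in generated by dietniche::study_fixture(seed = 101); not real survey data
pool_id	species	site	habitat	elevation_m	n_individuals
JAR_TC	Sceloporus jarrovii	Turkey Creek	Madrean Pine-oak	2070	42
JAR_BP	Sceloporus jarrovii	Barfoot Park	Montane Conifer Forest	2505	39
SLE_AWRR	Sceloporus slevini	Appleton-Whittell Research Ranch	Semi-desert Grassland	1430	32
SLE_BP	Sceloporus slevini	Barfoot Park	Montane Conifer Forest	2505	38
VIR_CC	Sceloporus virgatus	Cave Creek Canyon	Madrean Oak Woodland	1700	44
VIR_TC	Sceloporus virgatus	Turkey Creek	Madrean Pine-oak	2070	33
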