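# synthetic stand-in generated by dietniche::study_fixture(seed = 101); not real survey data
otu_id	JAR_TC	JAR_BP	SLE_AWRR	SLE_BP	VIR_CC	VIR_TC	taxonomy	confidence
OTU_01	0	0	39	0	0	0	p__Arthropoda;c__Arachnida;o__Araneae	0.909
OTU_02	0	0	0	95	0	0	p__Arthropoda;c__Arachnida;o__Araneae;f__Lycosidae	0.828
OTU_03	0	0	0	28	0	68	p__Arthropoda;c__Arachnida;o__Araneae;f__Salticidae;g__Phidippus	0.747
OTU_04	0	0	0	0	74	0	p__Arthropoda;c__Arachnida;o__Araneae;f__Thomisidae;g__Xysticus;s__arizonensis	0.936
OTU_05	0	0	0	0	0	177	p__Arthropoda;c__Arachnida;o__Araneae	0.855
OTU_06	0	101	0	0	0	0	p__Arthropoda;c__Insecta;o__Coleoptera;f__Elateridae	0.774
OTU_07	0	49	0	0	0	0	p__Arthropoda;c__Insecta;o__Coleoptera;f__Scarabaeidae;g__Phyllophaga	0.963
OTU_08	137	0	0	0	0	44	p__Arthropoda;c__Insecta;o__Coleoptera;f__Carabidae;g__Harpalus;s__chiricahuae	0.882
OTU_09	0	0	92	0	0	0	p__Arthropoda;c__Insecta;o__Coleoptera	0.801
OTU_10	0	0	25	0	0	0	p__Arthropoda;c__Insecta;o__Coleoptera;f__Curculionidae	0.72
OTU_11	0	0	0	0	228	0	p__Arthropoda;c__Insecta;o__Coleoptera;f__Elateridae;g__Limonius	0.909
OTU_12	0	0	0	0	0	13	p__Arthropoda;c__Insecta;o__Coleoptera;f__Scarabaeidae;g__Phyllophaga;s__sonorae	0.828
OTU_13	0	43	0	0	45	0	p__Arthropoda;c__Insecta;o__Diptera	0.747
OTU_14	0	0	0	23	0	0	p__Arthropoda;c__Insecta;o__Diptera;f__Cecidomyiidae	0.936
OTU_15	0	0	0	0	0	58	p__Arthropoda;c__Insecta;o__Diptera;f__Tachinidae;g__Tachina	0.855
OTU_16	0	0	0	0	0	24	p__Arthropoda;c__Insecta;o__Diptera;f__Muscidae;g__Musca;s__cochisei	0.774
OTU_17	0	0	0	7	0	0	p__Arthropoda;c__Insecta;o__Hemiptera	0.963
OTU_18	0	0	0	0	0	46	p__Arthropoda;c__Insecta;o__Hemiptera;f__Rhopalidae	0.882
OTU_19	0	0	0	111	0	0	p__Arthropoda;c__Insecta;o__Hymenoptera;f__Formicidae;g__Formica	0.801
OTU_20	0	0	0	0	42	0	p__Arthropoda;c__Insecta;o__Hymenoptera;f__Formicidae;g__Formica;s__madrensis	0.72
OTU_21	13	0	0	0	0	115	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Armadillidiidae	0.909
OTU_22	0	0	0	0	0	13	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Porcellionidae;g__Porcellio	0.828
OTU_23	0	0	0	0	0	87	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Armadillidiidae;g__Armadillidium;s__apachensis	0.747
OTU_24	0	0	0	0	0	48	p__Arthropoda;c__Malacostraca;o__Isopoda	0.936
OTU_25	0	0	0	0	0	87	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Porcellionidae	0.855
OTU_26	0	0	0	0	0	90	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Armadillidiidae;g__Armadillidium	0.774
OTU_27	0	0	0	0	0	134	p__Arthropoda;c__Malacostraca;o__Isopoda;f__Porcellionidae;g__Porcellio;s__huachucae	0.963
OTU_28	0	72	0	0	0	0	p__Arthropoda;c__Insecta;o__Lepidoptera	0.882
OTU_29	0	150	0	0	0	0	p__Arthropoda;c__Insecta;o__Lepidoptera;f__Geometridae	0.801
OTU_30	0	7	0	0	0	0	p__Arthropoda;c__Insecta;o__Lepidoptera;f__Noctuidae;g__Euxoa	0.72
OTU_31	0	179	0	0	0	0	p__Arthropoda;c__Insecta;o__Lepidoptera;f__Erebidae;g__Drasteria;s__pinaleno	0.909
OTU_32	0	26	0	0	0	0	p__Arthropoda;c__Insecta;o__Lepidoptera	0.828
OTU_33	0	65	0	0	0	0	p__Arthropoda;c__Insecta;o__Orthoptera;f__Acrididae	0.747
OTU_34	0	137	0	0	10	0	p__Arthropoda;c__Insecta;o__Orthoptera;f__Gryllidae;g__Gryllus	0.936
OTU_35	85	0	0	0	0	0	p__Arthropoda;c__Insecta;o__Orthoptera;f__Tettigoniidae;g__Scudderia;s__santaritae	0.855
OTU_36	0	0	0	0	88	0	p__Arthropoda;c__Insecta;o__Orthoptera	0.774
OTU_37	0	0	0	0	117	0	p__Arthropoda;c__Insecta;o__Orthoptera;f__Acrididae	0.963
OTU_38	0	0	0	0	5	0	p__Arthropoda;c__Insecta;o__Orthoptera;f__Gryllidae;g__Gryllus	0.882
OTU_39	0	0	0	0	0	34	p__Arthropoda;c__Insecta;o__Orthoptera;f__Tettigoniidae;g__Scudderia;s__animasensis	0.801
OTU_40	0	0	0	0	0	18	p__Arthropoda;c__Insecta;o__Orthoptera	0.72
OTU_41	0	0	0	0	0	82	p__Arthropoda;c__Insecta;o__Orthoptera;f__Acrididae	0.909
OTU_42	0	0	0	0	0	96	p__Arthropoda;c__Insecta;o__Orthoptera;f__Gryllidae;g__Gryllus	0.828
OTU_43	0	27	0	0	0	0	p__Arthropoda;c__Insecta	0.747
OTU_44	41	0	0	0	0	0	p__Arthropoda;c__Insecta	0.936
OTU_45	0	0	12	0	0	0	p__Arthropoda;c__Insecta	0.855
OTU_46	0	0	17	0	0	0	p__Arthropoda;c__Insecta	0.774
OTU_47	0	0	0	41	0	0	p__Arthropoda;c__Insecta	0.963
OTU_48	0	0	0	97	0	0	p__Arthropoda;c__Insecta	0.882
OTU_49	0	0	0	14	0	0	p__Arthropoda;c__Insecta	0.801
OTU_50	0	0	0	0	115	0	p__Arthropoda;c__Insecta	0.72
OTU_51	0	0	0	0	0	19	p__Arthropoda;c__Insecta	0.909
OTU_52	476	1249	0	0	0	0	p__Chordata;c__Reptilia;o__Squamata;f__Phrynosomatidae;g__Sceloporus;s__jarrovii	0.99
OTU_53	0	0	0	0	1305	263	p__Chordata;c__Reptilia;o__Squamata;f__Phrynosomatidae;g__Sceloporus;s__virgatus	0.99
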