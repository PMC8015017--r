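drug_name	drug_class	drug_total	n	ror	ror_ci_low	ror_ci_high	prr	chi2	ic	ic_ci_low	ic_ci_high	ror_signal	prr_signal	ic_signal	grand_total	event_set_name
Haloperidol	typical	939	3	81.79	25.76	259.68	80.89	158.65	1.95	-1.47	5.36	TRUE	TRUE	FALSE	703846	hyperprolactinaemia
Bromperidol	typical	113	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Pipamperone	typical	15	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Spiperone	typical	0	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Timiperone	typical	9	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Propericiazine	typical	85	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Prochlorperazine	typical	143	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Perphenazine	typical	17	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Fluphenazine	typical	89	4	149.56	54.48	410.63	146.59	424.31	2.28	-0.8	5.36	TRUE	TRUE	FALSE	703846	hyperprolactinaemia
Levomepromazine	typical	730	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Chlorpromazine	typical	431	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Sulpiride	typical	1395	13	283.29	156.78	511.89	273.74	2840.96	3.73	1.81	5.65	TRUE	TRUE	TRUE	703846	hyperprolactinaemia
Sultopride	typical	52	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Nemonapride	typical	9	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Pimozide	typical	39	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Perospirone	atypical	416	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Risperidone	atypical	2629	13	190.01	105.46	342.34	185.67	1919.94	3.69	1.78	5.61	TRUE	TRUE	TRUE	703846	hyperprolactinaemia
Paliperidone	atypical	774	23	1187.33	728.48	1935.18	1050.9	17778.71	4.54	2.96	6.12	TRUE	TRUE	TRUE	703846	hyperprolactinaemia
Blonanserin	atypical	550	5	184.22	74.16	457.61	179.78	683.21	2.54	-0.29	5.37	TRUE	TRUE	FALSE	703846	hyperprolactinaemia
Olanzapine	atypical	1825	4	60.79	22.27	165.95	60.3	170.62	2.22	-0.83	5.28	TRUE	TRUE	FALSE	703846	hyperprolactinaemia
Quetiapine	atypical	1836	1	15.24	2.12	109.53	15.21	2.84	0.91	-3.85	5.66	TRUE	FALSE	FALSE	703846	hyperprolactinaemia
Clozapine	atypical	1283	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Asenapine	atypical	134	2	188.96	45.76	780.12	184.14	200.09	1.57	-2.39	5.53	TRUE	FALSE	FALSE	703846	hyperprolactinaemia
Aripiprazole	atypical	2316	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Brexpiprazole	atypical	112	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Zotepine	atypical	279	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Mosapramine	atypical	4	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Oxypertine	atypical	6	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
Clocapramine	atypical	0	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	hyperprolactinaemia
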