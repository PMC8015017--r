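drug_name	drug_class	drug_total	n	ror	ror_ci_low	ror_ci_high	prr	chi2	ic	ic_ci_low	ic_ci_high	ror_signal	prr_signal	ic_signal	grand_total	event_set_name
Haloperidol	typical	939	1	0.49	0.07	3.51	0.49	0.13	-0.6	-5.3	4.11	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Bromperidol	typical	113	1	4.14	0.58	29.68	4.11	0.27	0.58	-4.06	5.43	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Pipamperone	typical	15	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Spiperone	typical	0	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Timiperone	typical	9	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Propericiazine	typical	85	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Prochlorperazine	typical	143	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Perphenazine	typical	17	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Fluphenazine	typical	89	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Levomepromazine	typical	730	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Chlorpromazine	typical	431	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Sulpiride	typical	1395	12	4.05	2.29	7.16	4.02	24.15	1.7	-0.16	3.56	TRUE	TRUE	FALSE	703846	benign_and_malignant_breast_neoplasms
Sultopride	typical	52	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Nemonapride	typical	9	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Pimozide	typical	39	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Perospirone	atypical	416	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Risperidone	atypical	2629	11	1.95	1.08	3.54	1.95	4.17	0.84	-1.08	2.78	TRUE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Paliperidone	atypical	774	2	2.37	0.59	9.53	2.37	0.51	0.7	-3.16	4.55	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Blonanserin	atypical	550	4	3.4	1.27	9.11	3.39	4.54	1.19	-1.8	4.19	TRUE	TRUE	FALSE	703846	benign_and_malignant_breast_neoplasms
Olanzapine	atypical	1825	2	0.51	0.07	3.51	0.5	0.52	-0.72	-4.56	3.13	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Quetiapine	atypical	1836	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Clozapine	atypical	1283	11	4.03	2.22	7.31	4.01	21.77	1.67	-0.26	3.61	TRUE	TRUE	FALSE	703846	benign_and_malignant_breast_neoplasms
Asenapine	atypical	134	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Aripiprazole	atypical	2316	6	1.36	0.61	3.03	1.36	0.26	0.37	-2.15	2.89	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Brexpiprazole	atypical	112	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Zotepine	atypical	279	5	8.48	3.5	20.58	8.35	25.39	1.94	-0.84	4.65	TRUE	TRUE	FALSE	703846	benign_and_malignant_breast_neoplasms
Mosapramine	atypical	4	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Oxypertine	atypical	6	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
Clocapramine	atypical	0	0	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	FALSE	FALSE	703846	benign_and_malignant_breast_neoplasms
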