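drug_name	drug_class
Haloperidol	typical
Bromperidol	typical
Pipamperone	typical
Spiperone	typical
Timiperone	typical
Propericiazine	typical
Prochlorperazine	typical
Perphenazine	typical
Fluphenazine	typical
Levomepromazine	typical
Chlorpromazine	typical
Sulpiride	typical
Sultopride	typical
Nemonapride	typical
Pimozide	typical
Perospirone	atypical
Risperidone	atypical
Paliperidone	atypical
Blonanserin	atypical
Olanzapine	atypical
Quetiapine	atypical
Clozapine	atypical
Asenapine	atypical
Aripiprazole	atypical
Brexpiprazole	atypical
Zotepine	atypical
Mosapramine	atypical
Oxypertine	atypical
Clocapramine	atypical
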