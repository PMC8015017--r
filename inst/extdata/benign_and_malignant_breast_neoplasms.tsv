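pt_name	pt_code
Benign breast neoplasm	10004243
Breast cancer	10006187
Breast cancer in situ	10006189
Breast cancer recurrent	10006198
Breast cancer stage I	10006199
Breast cancer stage II	10006200
Breast cancer stage III	10006201
Breast cancer stage IV	10006202
Breast cyst	10006220
Breast hyperplasia	10006256
Breast neoplasm	10006279
Fibroadenoma of breast	10016613
Fibrocystic breast disease	10016621
Haemangioma of breast	10018820
Inflammatory carcinoma of breast recurrent	10021977
Inflammatory carcinoma of breast stage III	10021978
Inflammatory carcinoma of breast stage IV	10021979
Inflammatory carcinoma of the breast	10021980
Intraductal papilloma of breast	10022781
Lipoma of breast	10024616
Medullary carcinoma of breast	10027095
Metastases to breast	10027454
Paget's disease of nipple	10033364
Malignant nipple neoplasm male	10053128
Malignant nipple neoplasm female	10053129
Breast cancer metastatic	10055113
Nipple neoplasm	10056286
Breast cancer female	10057654
Breast cancer male	10061020
Malignant nipple neoplasm	10062051
Breast adenoma	10063087
Breast fibroma	10063088
HER2 positive breast cancer	10065430
Apocrine breast carcinoma	10066206
Breast sarcoma	10068582
Breast sarcoma metastatic	10068583
Breast sarcoma recurrent	10068584
Oestrogen receptor positive breast cancer	10070577
Phyllodes tumour	10071776
Benign nipple neoplasm	10072040
Breast cyst rupture	10072812
Breast angiosarcoma	10072813
Breast angiosarcoma metastatic	10072814
Intraductal proliferative breast lesion	10073094
Invasive ductal breast carcinoma	10073095
Invasive lobular breast carcinoma	10073096
Invasive papillary breast carcinoma	10073098
Lobular breast carcinoma in situ	10073099
Metaplastic breast carcinoma	10073100
Mucinous breast carcinoma	10073101
Neuroendocrine breast tumour	10073103
Tubular breast carcinoma	10073104
Intraductal papillary breast neoplasm	10073540
Triple negative breast cancer	10075566
Invasive breast carcinoma	10075713
Hormone refractory breast cancer	10076935
Haemorrhagic breast cyst	10077443
Intracystic breast papilloma	10078162
Squamous cell breast carcinoma	10079307
Primary breast lymphoma	10081036
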