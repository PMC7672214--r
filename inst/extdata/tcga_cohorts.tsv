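cancer_type	kraken	shogun
Adrenocortical carcinoma	79	79
Bladder urothelial carcinoma	729	729
Brain lower grade glioma	731	731
Breast invasive carcinoma	1483	1483
Cervical squamous cell carcinoma and endocervical adenocarcinoma	451	451
Cholangiocarcinoma	45	45
Colon adenocarcinoma	1006	417
Esophageal carcinoma	340	340
Glioblastoma multiforme	489	338
Head and Neck squamous cell carcinoma	906	297
Kidney chromophobe	191	65
Kidney renal clear cell carcinoma	1141	1114
Kidney renal papillary cell carcinoma	393	23
Liver hepatocellular carcinoma	523	162
Lung adenocarcinoma	911	911
Lung squamous cell carcinoma	638	534
Lymphoid neoplasm diffuse large b-cell lymphoma	61	61
Mesothelioma	87	87
Ovarian serous cystadenocarcinoma	1031	1031
Pancreatic adenocarcinoma	183	183
Pheochromocytoma and Paraganglioma	186	186
Prostate adenocarcinoma	829	829
Rectum adenocarcinoma	372	372
Sarcoma	347	347
Skin cutaneous melanoma	792	667
Stomach adenocarcinoma	1079	1079
Testicular germ cell tumors	139	139
Thymoma	122	122
Thyroid carcinoma	880	287
Uterine carcinosarcoma	57	57
Uterine corpus endometrial carcinoma	1222	169
Uveal melanoma	182	182
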