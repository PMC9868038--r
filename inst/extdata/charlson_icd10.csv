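category,icd10_prefix,weight,hierarchy
myocardial_infarction,I21,1,
myocardial_infarction,I22,1,
myocardial_infarction,I252,1,
congestive_heart_failure,I099,1,
congestive_heart_failure,I110,1,
congestive_heart_failure,I130,1,
congestive_heart_failure,I132,1,
congestive_heart_failure,I255,1,
congestive_heart_failure,I420,1,
congestive_heart_failure,I425,1,
congestive_heart_failure,I426,1,
congestive_heart_failure,I427,1,
congestive_heart_failure,I428,1,
congestive_heart_failure,I429,1,
congestive_heart_failure,I43,1,
congestive_heart_failure,I50,1,
congestive_heart_failure,P290,1,
peripheral_vascular,I70,1,
peripheral_vascular,I71,1,
peripheral_vascular,I731,1,
peripheral_vascular,I738,1,
peripheral_vascular,I739,1,
peripheral_vascular,I771,1,
peripheral_vascular,I790,1,
peripheral_vascular,I792,1,
peripheral_vascular,K551,1,
peripheral_vascular,K558,1,
peripheral_vascular,K559,1,
peripheral_vascular,Z958,1,
peripheral_vascular,Z959,1,
cerebrovascular,G45,1,
cerebrovascular,G46,1,
cerebrovascular,H340,1,
cerebrovascular,I60,1,
cerebrovascular,I61,1,
cerebrovascular,I62,1,
cerebrovascular,I63,1,
cerebrovascular,I64,1,
cerebrovascular,I65,1,
cerebrovascular,I66,1,
cerebrovascular,I67,1,
cerebrovascular,I68,1,
cerebrovascular,I69,1,
dementia,F00,1,
dementia,F01,1,
dementia,F02,1,
dementia,F03,1,
dementia,F051,1,
dementia,G30,1,
dementia,G311,1,
chronic_pulmonary,I278,1,
chronic_pulmonary,I279,1,
chronic_pulmonary,J40,1,
chronic_pulmonary,J41,1,
chronic_pulmonary,J42,1,
chronic_pulmonary,J43,1,
chronic_pulmonary,J44,1,
chronic_pulmonary,J45,1,
chronic_pulmonary,J46,1,
chronic_pulmonary,J47,1,
chronic_pulmonary,J60,1,
chronic_pulmonary,J61,1,
chronic_pulmonary,J62,1,
chronic_pulmonary,J63,1,
chronic_pulmonary,J64,1,
chronic_pulmonary,J65,1,
chronic_pulmonary,J66,1,
chronic_pulmonary,J67,1,
chronic_pulmonary,J684,1,
chronic_pulmonary,J701,1,
chronic_pulmonary,J703,1,
rheumatic,M05,1,
rheumatic,M06,1,
rheumatic,M315,1,
rheumatic,M32,1,
rheumatic,M33,1,
rheumatic,M34,1,
rheumatic,M351,1,
rheumatic,M353,1,
rheumatic,M360,1,
peptic_ulcer,K25,1,
peptic_ulcer,K26,1,
peptic_ulcer,K27,1,
peptic_ulcer,K28,1,
mild_liver,B18,1,liver
mild_liver,K700,1,liver
mild_liver,K701,1,liver
mild_liver,K702,1,liver
mild_liver,K703,1,liver
mild_liver,K709,1,liver
mild_liver,K713,1,liver
mild_liver,K714,1,liver
mild_liver,K715,1,liver
mild_liver,K717,1,liver
mild_liver,K73,1,liver
mild_liver,K74,1,liver
mild_liver,K760,1,liver
mild_liver,K762,1,liver
mild_liver,K763,1,liver
mild_liver,K764,1,liver
mild_liver,K768,1,liver
mild_liver,K769,1,liver
mild_liver,Z944,1,liver
diabetes_uncomplicated,E100,1,diabetes
diabetes_uncomplicated,E110,1,diabetes
diabetes_uncomplicated,E120,1,diabetes
diabetes_uncomplicated,E130,1,diabetes
diabetes_uncomplicated,E140,1,diabetes
diabetes_uncomplicated,E101,1,diabetes
diabetes_uncomplicated,E111,1,diabetes
diabetes_uncomplicated,E121,1,diabetes
diabetes_uncomplicated,E131,1,diabetes
diabetes_uncomplicated,E141,1,diabetes
diabetes_uncomplicated,E106,1,diabetes
diabetes_uncomplicated,E116,1,diabetes
diabetes_uncomplicated,E126,1,diabetes
diabetes_uncomplicated,E136,1,diabetes
diabetes_uncomplicated,E146,1,diabetes
diabetes_uncomplicated,E108,1,diabetes
diabetes_uncomplicated,E118,1,diabetes
diabetes_uncomplicated,E128,1,diabetes
diabetes_uncomplicated,E138,1,diabetes
diabetes_uncomplicated,E148,1,diabetes
diabetes_uncomplicated,E109,1,diabetes
diabetes_uncomplicated,E119,1,diabetes
diabetes_uncomplicated,E129,1,diabetes
diabetes_uncomplicated,E139,1,diabetes
diabetes_uncomplicated,E149,1,diabetes
diabetes_complicated,E102,2,diabetes
diabetes_complicated,E112,2,diabetes
diabetes_complicated,E122,2,diabetes
diabetes_complicated,E132,2,diabetes
diabetes_complicated,E142,2,diabetes
diabetes_complicated,E103,2,diabetes
diabetes_complicated,E113,2,diabetes
diabetes_complicated,E123,2,diabetes
diabetes_complicated,E133,2,diabetes
diabetes_complicated,E143,2,diabetes
diabetes_complicated,E104,2,diabetes
diabetes_complicated,E114,2,diabetes
diabetes_complicated,E124,2,diabetes
diabetes_complicated,E134,2,diabetes
diabetes_complicated,E144,2,diabetes
diabetes_complicated,E105,2,diabetes
diabetes_complicated,E115,2,diabetes
diabetes_complicated,E125,2,diabetes
diabetes_complicated,E135,2,diabetes
diabetes_complicated,E145,2,diabetes
diabetes_complicated,E107,2,diabetes
diabetes_complicated,E117,2,diabetes
diabetes_complicated,E127,2,diabetes
diabetes_complicated,E137,2,diabetes
diabetes_complicated,E147,2,diabetes
hemiplegia,G041,2,
hemiplegia,G114,2,
hemiplegia,G801,2,
hemiplegia,G802,2,
hemiplegia,G81,2,
hemiplegia,G82,2,
hemiplegia,G830,2,
hemiplegia,G831,2,
hemiplegia,G832,2,
hemiplegia,G833,2,
hemiplegia,G834,2,
hemiplegia,G839,2,
renal,I120,2,
renal,I131,2,
renal,N032,2,
renal,N033,2,
renal,N034,2,
renal,N035,2,
renal,N036,2,
renal,N037,2,
renal,N052,2,
renal,N053,2,
renal,N054,2,
renal,N055,2,
renal,N056,2,
renal,N057,2,
renal,N18,2,
renal,N19,2,
renal,N250,2,
renal,Z490,2,
renal,Z491,2,
renal,Z492,2,
renal,Z940,2,
renal,Z992,2,
malignancy,C00,2,cancer
malignancy,C01,2,cancer
malignancy,C02,2,cancer
malignancy,C03,2,cancer
malignancy,C04,2,cancer
malignancy,C05,2,cancer
malignancy,C06,2,cancer
malignancy,C07,2,cancer
malignancy,C08,2,cancer
malignancy,C09,2,cancer
malignancy,C10,2,cancer
malignancy,C11,2,cancer
malignancy,C12,2,cancer
malignancy,C13,2,cancer
malignancy,C14,2,cancer
malignancy,C15,2,cancer
malignancy,C16,2,cancer
malignancy,C17,2,cancer
malignancy,C18,2,cancer
malignancy,C19,2,cancer
malignancy,C20,2,cancer
malignancy,C21,2,cancer
malignancy,C22,2,cancer
malignancy,C23,2,cancer
malignancy,C24,2,cancer
malignancy,C25,2,cancer
malignancy,C26,2,cancer
malignancy,C30,2,cancer
malignancy,C31,2,cancer
malignancy,C32,2,cancer
malignancy,C33,2,cancer
malignancy,C34,2,cancer
malignancy,C37,2,cancer
malignancy,C38,2,cancer
malignancy,C39,2,cancer
malignancy,C40,2,cancer
malignancy,C41,2,cancer
malignancy,C43,2,cancer
malignancy,C45,2,cancer
malignancy,C46,2,cancer
malignancy,C47,2,cancer
malignancy,C48,2,cancer
malignancy,C49,2,cancer
malignancy,C50,2,cancer
malignancy,C51,2,cancer
malignancy,C52,2,cancer
malignancy,C53,2,cancer
malignancy,C54,2,cancer
malignancy,C55,2,cancer
malignancy,C56,2,cancer
malignancy,C57,2,cancer
malignancy,C58,2,cancer
malignancy,C60,2,cancer
malignancy,C61,2,cancer
malignancy,C62,2,cancer
malignancy,C63,2,cancer
malignancy,C64,2,cancer
malignancy,C65,2,cancer
malignancy,C66,2,cancer
malignancy,C67,2,cancer
malignancy,C68,2,cancer
malignancy,C69,2,cancer
malignancy,C70,2,cancer
malignancy,C71,2,cancer
malignancy,C72,2,cancer
malignancy,C73,2,cancer
malignancy,C74,2,cancer
malignancy,C75,2,cancer
malignancy,C76,2,cancer
malignancy,C81,2,cancer
malignancy,C82,2,cancer
malignancy,C83,2,cancer
malignancy,C84,2,cancer
malignancy,C85,2,cancer
malignancy,C88,2,cancer
malignancy,C90,2,cancer
malignancy,C91,2,cancer
malignancy,C92,2,cancer
malignancy,C93,2,cancer
malignancy,C94,2,cancer
malignancy,C95,2,cancer
malignancy,C96,2,cancer
malignancy,C97,2,cancer
moderate_severe_liver,I850,3,liver
moderate_severe_liver,I859,3,liver
moderate_severe_liver,I864,3,liver
moderate_severe_liver,I982,3,liver
moderate_severe_liver,K704,3,liver
moderate_severe_liver,K711,3,liver
moderate_severe_liver,K721,3,liver
moderate_severe_liver,K729,3,liver
moderate_severe_liver,K765,3,liver
moderate_severe_liver,K766,3,liver
moderate_severe_liver,K767,3,liver
metastatic_tumor,C77,6,cancer
metastatic_tumor,C78,6,cancer
metastatic_tumor,C79,6,cancer
metastatic_tumor,C80,6,cancer
hiv,B20,6,
hiv,B21,6,
hiv,B22,6,
hiv,B24,6,
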