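condition,icd10_prefix,charlson,weight
mi,I21,TRUE,1
mi,I22,TRUE,1
mi,I25.2,TRUE,1
chf,I50,TRUE,1
chf,I11.0,TRUE,1
pvd,I70,TRUE,1
pvd,I71,TRUE,1
pvd,I73.1,TRUE,1
pvd,I73.9,TRUE,1
pvd,I77.1,TRUE,1
pvd,K55.1,TRUE,1
pvd,Z95.8,TRUE,1
cerebrovascular,I64,TRUE,1
cerebrovascular,G45,TRUE,1
cerebrovascular,G46,TRUE,1
cerebrovascular,I60,TRUE,1
cerebrovascular,I61,TRUE,1
cerebrovascular,I62,TRUE,1
cerebrovascular,I63,TRUE,1
cerebrovascular,I65,TRUE,1
cerebrovascular,I66,TRUE,1
cerebrovascular,I67,TRUE,1
cerebrovascular,I69,TRUE,1
dementia,F00,TRUE,1
dementia,F01,TRUE,1
dementia,F02,TRUE,1
dementia,F03,TRUE,1
dementia,G30,TRUE,1
pulmonary,J44,TRUE,1
pulmonary,J40,TRUE,1
pulmonary,J41,TRUE,1
pulmonary,J42,TRUE,1
pulmonary,J43,TRUE,1
pulmonary,J45,TRUE,1
pulmonary,J46,TRUE,1
pulmonary,J47,TRUE,1
pulmonary,J60,TRUE,1
pulmonary,J61,TRUE,1
pulmonary,J62,TRUE,1
pulmonary,J63,TRUE,1
pulmonary,J64,TRUE,1
pulmonary,J65,TRUE,1
pulmonary,J66,TRUE,1
pulmonary,J67,TRUE,1
rheumatic,M05,TRUE,1
rheumatic,M06,TRUE,1
rheumatic,M32,TRUE,1
rheumatic,M33,TRUE,1
rheumatic,M34,TRUE,1
peptic_ulcer,K25,TRUE,1
peptic_ulcer,K26,TRUE,1
peptic_ulcer,K27,TRUE,1
peptic_ulcer,K28,TRUE,1
liver_mild,K70.3,TRUE,1
liver_mild,B18,TRUE,1
liver_mild,K70.0,TRUE,1
liver_mild,K70.1,TRUE,1
liver_mild,K70.2,TRUE,1
liver_mild,K70.9,TRUE,1
liver_mild,K73,TRUE,1
liver_mild,K74,TRUE,1
liver_mild,K76.0,TRUE,1
diabetes,E11.9,TRUE,1
diabetes,E10.0,TRUE,1
diabetes,E10.1,TRUE,1
diabetes,E10.9,TRUE,1
diabetes,E11.0,TRUE,1
diabetes,E11.1,TRUE,1
diabetes,E13.0,TRUE,1
diabetes,E13.1,TRUE,1
diabetes,E13.9,TRUE,1
diabetes,E14.0,TRUE,1
diabetes,E14.1,TRUE,1
diabetes,E14.9,TRUE,1
diabetes_complications,E11.2,TRUE,2
diabetes_complications,E10.2,TRUE,2
diabetes_complications,E10.3,TRUE,2
diabetes_complications,E10.4,TRUE,2
diabetes_complications,E10.5,TRUE,2
diabetes_complications,E10.7,TRUE,2
diabetes_complications,E11.3,TRUE,2
diabetes_complications,E11.4,TRUE,2
diabetes_complications,E11.5,TRUE,2
diabetes_complications,E11.7,TRUE,2
diabetes_complications,E13.2,TRUE,2
diabetes_complications,E14.2,TRUE,2
paraplegia,G82,TRUE,2
paraplegia,G04.1,TRUE,2
paraplegia,G81,TRUE,2
paraplegia,G83.0,TRUE,2
renal,N18,TRUE,2
renal,I12.0,TRUE,2
renal,I13.1,TRUE,2
renal,N03,TRUE,2
renal,N19,TRUE,2
renal,N25.0,TRUE,2
renal,Z49,TRUE,2
renal,Z94.0,TRUE,2
renal,Z99.2,TRUE,2
cancer,C34,TRUE,2
cancer,C0,TRUE,2
cancer,C1,TRUE,2
cancer,C2,TRUE,2
cancer,C30,TRUE,2
cancer,C31,TRUE,2
cancer,C32,TRUE,2
cancer,C33,TRUE,2
cancer,C37,TRUE,2
cancer,C38,TRUE,2
cancer,C39,TRUE,2
cancer,C40,TRUE,2
cancer,C41,TRUE,2
cancer,C43,TRUE,2
cancer,C45,TRUE,2
cancer,C46,TRUE,2
cancer,C47,TRUE,2
cancer,C48,TRUE,2
cancer,C49,TRUE,2
cancer,C5,TRUE,2
cancer,C6,TRUE,2
cancer,C70,TRUE,2
cancer,C71,TRUE,2
cancer,C72,TRUE,2
cancer,C73,TRUE,2
cancer,C74,TRUE,2
cancer,C75,TRUE,2
cancer,C76,TRUE,2
cancer,C81,TRUE,2
cancer,C82,TRUE,2
cancer,C83,TRUE,2
cancer,C84,TRUE,2
cancer,C85,TRUE,2
cancer,C88,TRUE,2
cancer,C90,TRUE,2
cancer,C91,TRUE,2
cancer,C92,TRUE,2
cancer,C93,TRUE,2
cancer,C94,TRUE,2
cancer,C95,TRUE,2
cancer,C96,TRUE,2
liver_severe,K72.9,TRUE,3
liver_severe,K70.4,TRUE,3
liver_severe,K71.1,TRUE,3
liver_severe,K72.1,TRUE,3
liver_severe,K76.5,TRUE,3
liver_severe,K76.6,TRUE,3
liver_severe,K76.7,TRUE,3
liver_severe,I85,TRUE,3
metastatic,C78,TRUE,6
metastatic,C77,TRUE,6
metastatic,C79,TRUE,6
metastatic,C80,TRUE,6
hiv,B20,TRUE,6
hiv,B21,TRUE,6
hiv,B22,TRUE,6
hiv,B24,TRUE,6
osteoporosis,M81,FALSE,0
osteoporosis,M80,FALSE,0
parkinsons,G20,FALSE,0
parkinsons,G21,FALSE,0
parkinsons,G22,FALSE,0
vision_impairment,H54,FALSE,0
deafness,H90,FALSE,0
deafness,H91,FALSE,0
delirium,F05.0,FALSE,0
delirium,F05.9,FALSE,0
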