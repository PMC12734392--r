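variable,level,group,count
gender,Male,mucosa,27
gender,Male,normal,71
gender,Male,tumor,71
gender,Female,mucosa,23
gender,Female,normal,27
gender,Female,tumor,27
location,Left,mucosa,23
location,Left,normal,60
location,Left,tumor,60
location,Right,mucosa,27
location,Right,normal,38
location,Right,tumor,38
hospital,Aberdeen,low,10
hospital,Aberdeen,high,14
hospital,Barcelona,low,41
hospital,Barcelona,high,11
hospital,Florence,low,17
hospital,Florence,high,0
hospital,SVH_Dublin,low,34
hospital,SVH_Dublin,high,10
tumor_stage,pT4,low,3
tumor_stage,pT4,high,6
tumor_stage,pT3,low,77
tumor_stage,pT3,high,22
tumor_stage,pT2,low,5
tumor_stage,pT2,high,1
tumor_stage,pT4a,low,8
tumor_stage,pT4a,high,2
tumor_stage,pT4b,low,8
tumor_stage,pT4b,high,4
tumor_stage,pT1,low,1
tumor_stage,pT1,high,0
nodule_stage,pN0,low,57
nodule_stage,pN0,high,17
nodule_stage,pN1,low,20
nodule_stage,pN1,high,5
nodule_stage,pN2,low,5
nodule_stage,pN2,high,3
nodule_stage,pN2a,low,3
nodule_stage,pN2a,high,2
nodule_stage,pN1a,low,8
nodule_stage,pN1a,high,4
nodule_stage,pN1b,low,6
nodule_stage,pN1b,high,2
nodule_stage,pN2b,low,3
nodule_stage,pN2b,high,2
metastasis,pMx,low,35
metastasis,pMx,high,22
metastasis,pM0,low,67
metastasis,pM0,high,13
cms,CMS1,low,6
cms,CMS1,high,17
cms,CMS2,low,50
cms,CMS2,high,2
cms,CMS4,low,18
cms,CMS4,high,4
cms,CMS3,low,16
cms,CMS3,high,6
braf_v600e,WT,low,102
braf_v600e,WT,high,20
braf_v600e,MT,low,0
braf_v600e,MT,high,15
tp53,WT,low,40
tp53,WT,high,19
tp53,MT,low,62
tp53,MT,high,16
kras,MT,low,42
kras,MT,high,12
kras,WT,low,60
kras,WT,high,23
os_status,alive,low,60
os_status,alive,high,22
os_status,dead,low,42
os_status,dead,high,13
recurrence,no,low,73
recurrence,no,high,24
recurrence,yes,low,27
recurrence,yes,high,11
adjuvant_therapy,yes,low,42
adjuvant_therapy,yes,high,13
adjuvant_therapy,no,low,57
adjuvant_therapy,no,high,22
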