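name,chem_class,metabolite_group,matrix,unit,normalization,persistent,pct_detect,gm,gsd,in_table1
MBP,phthalate,DBP,urine,ug/g creatinine,creatinine,FALSE,100,26.0,1.9,TRUE
MiBP,phthalate,DBP,urine,ug/g creatinine,creatinine,FALSE,99,5.1,2.1,TRUE
MEP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,100,143.3,2.9,TRUE
MBzP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,98,10.3,2.4,TRUE
MCPP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,99,2.4,1.8,TRUE
MEHP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,89,5.2,2.7,TRUE
MEHHP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,100,41.0,2.4,TRUE
MEOHP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,100,25.0,2.4,FALSE
MECPP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,100,27.6,2.5,TRUE
BPA,phenol,none,urine,ug/g creatinine,creatinine,FALSE,96,2.1,1.9,TRUE
PCB-28,PCB,none,serum,ng/g lipid,lipid,TRUE,82,0.8,2.9,TRUE
PCB-44,PCB,none,serum,ng/g lipid,lipid,TRUE,8,0.2,2.5,FALSE
PCB-49,PCB,none,serum,ng/g lipid,lipid,TRUE,6,0.2,2.5,FALSE
PCB-52,PCB,none,serum,ng/g lipid,lipid,TRUE,11,0.3,2.6,FALSE
PCB-66,PCB,none,serum,ng/g lipid,lipid,TRUE,75,5.6,2.7,TRUE
PCB-74,PCB,none,serum,ng/g lipid,lipid,TRUE,99,2.8,1.8,TRUE
PCB-87,PCB,none,serum,ng/g lipid,lipid,TRUE,10,0.2,2.7,FALSE
PCB-99,PCB,none,serum,ng/g lipid,lipid,TRUE,99,2.8,1.8,TRUE
PCB-101,PCB,none,serum,ng/g lipid,lipid,TRUE,32,2.1,2.9,TRUE
PCB-105,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.1,2.5,TRUE
PCB-110,PCB,none,serum,ng/g lipid,lipid,TRUE,7,0.3,2.8,FALSE
PCB-118,PCB,none,serum,ng/g lipid,lipid,TRUE,99,4.9,2.0,TRUE
PCB-128,PCB,none,serum,ng/g lipid,lipid,TRUE,9,0.2,2.6,FALSE
PCB-138/158,PCB,none,serum,ng/g lipid,lipid,TRUE,99,7.8,2.0,TRUE
PCB-146,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.0,2.6,TRUE
PCB-149,PCB,none,serum,ng/g lipid,lipid,TRUE,11,0.2,2.7,FALSE
PCB-151,PCB,none,serum,ng/g lipid,lipid,TRUE,9,0.2,2.6,FALSE
PCB-153,PCB,none,serum,ng/g lipid,lipid,TRUE,100,11.1,1.9,TRUE
PCB-156,PCB,none,serum,ng/g lipid,lipid,TRUE,96,1.6,2.4,TRUE
PCB-157,PCB,none,serum,ng/g lipid,lipid,TRUE,51,3.3,3.2,TRUE
PCB-167,PCB,none,serum,ng/g lipid,lipid,TRUE,59,3.9,3.1,TRUE
PCB-170,PCB,none,serum,ng/g lipid,lipid,TRUE,100,2.8,2.2,TRUE
PCB-172,PCB,none,serum,ng/g lipid,lipid,TRUE,34,2.2,3.0,TRUE
PCB-177,PCB,none,serum,ng/g lipid,lipid,TRUE,61,4.0,3.1,TRUE
PCB-178,PCB,none,serum,ng/g lipid,lipid,TRUE,52,3.3,3.2,TRUE
PCB-180,PCB,none,serum,ng/g lipid,lipid,TRUE,100,2.0,2.2,FALSE
PCB-183,PCB,none,serum,ng/g lipid,lipid,TRUE,87,0.8,3.0,TRUE
PCB-187,PCB,none,serum,ng/g lipid,lipid,TRUE,98,2.1,2.3,TRUE
PCB-194,PCB,none,serum,ng/g lipid,lipid,TRUE,92,1.2,2.8,TRUE
PCB-195,PCB,none,serum,ng/g lipid,lipid,TRUE,39,2.4,3.1,TRUE
PCB-196/203,PCB,none,serum,ng/g lipid,lipid,TRUE,96,1.6,2.3,TRUE
PCB-199,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.2,2.8,TRUE
PCB-206,PCB,none,serum,ng/g lipid,lipid,TRUE,81,0.6,3.2,TRUE
PCB-209,PCB,none,serum,ng/g lipid,lipid,TRUE,35,2.2,3.0,TRUE
beta-HCH,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,27,1.9,2.8,TRUE
HCB,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,94,6.5,1.9,TRUE
pp-DDT,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,52,3.3,3.2,TRUE
pp-DDE,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,100,71.6,1.8,TRUE
Oxychlordane,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,90,4.4,2.5,TRUE
trans-Nonachlor,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,97,7.5,2.1,TRUE
Aldrin,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,4,0.3,2.4,FALSE
Dieldrin,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,12,1.1,2.3,FALSE
Heptachlor,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,5,0.4,2.5,FALSE
Mirex,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,10,0.6,2.8,FALSE
op-DDT,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,8,0.5,2.9,FALSE
BB-153,BFR,none,serum,ng/g lipid,lipid,TRUE,85,0.9,3.7,TRUE
PBDE-17,BFR,none,serum,ng/g lipid,lipid,TRUE,7,0.2,3.0,FALSE
PBDE-28,BFR,none,serum,ng/g lipid,lipid,TRUE,81,0.8,4.0,TRUE
PBDE-47,BFR,none,serum,ng/g lipid,lipid,TRUE,100,20.1,2.7,TRUE
PBDE-66,BFR,none,serum,ng/g lipid,lipid,TRUE,10,0.3,3.1,FALSE
PBDE-85,BFR,none,serum,ng/g lipid,lipid,TRUE,49,3.1,3.2,TRUE
PBDE-99,BFR,none,serum,ng/g lipid,lipid,TRUE,100,4.7,2.9,TRUE
PBDE-100,BFR,none,serum,ng/g lipid,lipid,TRUE,99,3.8,3.0,TRUE
PBDE-153,BFR,none,serum,ng/g lipid,lipid,TRUE,99,5.1,3.1,TRUE
PBDE-154,BFR,none,serum,ng/g lipid,lipid,TRUE,42,2.6,3.1,TRUE
PBDE-183,BFR,none,serum,ng/g lipid,lipid,TRUE,8,0.4,3.2,FALSE
PFOA,PFAS,none,serum,ug/L,none,TRUE,100,5.6,1.7,TRUE
PFOS,PFAS,none,serum,ug/L,none,TRUE,100,13.1,1.6,TRUE
PFNA,PFAS,none,serum,ug/L,none,TRUE,100,0.9,1.5,TRUE
PFHxS,PFAS,none,serum,ug/L,none,TRUE,100,1.5,2.0,TRUE
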