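name,chem_class,metabolite_group,matrix,unit,normalization,persistent,pct_detect,gm,gsd,p5,p25,p50,p75,p95,nhanes_median
MBP,phthalate,DBP,urine,ug/g creatinine,creatinine,FALSE,100,26.0,1.9,9.5,18,26,37,75,24
MiBP,phthalate,DBP,urine,ug/g creatinine,creatinine,FALSE,99,5.1,2.1,1.5,3.0,5.6,8.6,17,4.0
MEP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,100,143.3,2.9,25,70,133,286,1010,120
MBzP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,98,10.3,2.4,3.2,5.8,11,17,48,10
MCPP,phthalate,none,urine,ug/g creatinine,creatinine,FALSE,99,2.4,1.8,1.1,1.6,2.3,3.4,5.9,2.9
MEHP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,89,5.2,2.7,,2.9,4.4,7.5,41,2.2
MEHHP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,100,41.0,2.4,7.7,15,22,49,152,19
MECPP,phthalate,DEHP,urine,ug/g creatinine,creatinine,FALSE,100,27.6,2.5,13,21,35,70,191,31
BPA,phenol,none,urine,ug/g creatinine,creatinine,FALSE,96,2.1,1.9,0.8,1.4,2.0,3.1,6.6,2.7
PCB-28,PCB,none,serum,ng/g lipid,lipid,TRUE,82,0.8,2.9,,0.7,1.0,1.6,3.3,5.0
PCB-66,PCB,none,serum,ng/g lipid,lipid,TRUE,75,5.6,2.7,,,0.6,1.0,2.2,1.4
PCB-74,PCB,none,serum,ng/g lipid,lipid,TRUE,99,2.8,1.8,1.2,2.0,2.6,3.9,7.0,5.4
PCB-99,PCB,none,serum,ng/g lipid,lipid,TRUE,99,2.8,1.8,1.2,1.9,2.8,3.9,7.1,3.9
PCB-101,PCB,none,serum,ng/g lipid,lipid,TRUE,32,2.1,2.9,,,,0.5,1.5,1.6
PCB-105,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.1,2.5,,0.8,1.1,1.7,3.4,1.2
PCB-118,PCB,none,serum,ng/g lipid,lipid,TRUE,99,4.9,2.0,2.1,3.2,4.8,7.1,14,5.0
PCB-138/158,PCB,none,serum,ng/g lipid,lipid,TRUE,99,7.8,2.0,3.0,5.3,7.7,11,25,16
PCB-146,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.0,2.6,,0.8,1.1,1.7,4.1,2.3
PCB-153,PCB,none,serum,ng/g lipid,lipid,TRUE,100,11.1,1.9,4.3,7.6,11,15,35,22
PCB-156,PCB,none,serum,ng/g lipid,lipid,TRUE,96,1.6,2.4,0.5,1.0,1.6,2.5,6.1,3.4
PCB-157,PCB,none,serum,ng/g lipid,lipid,TRUE,51,3.3,3.2,,,0.4,0.7,1.6,0.9
PCB-167,PCB,none,serum,ng/g lipid,lipid,TRUE,59,3.9,3.1,,,0.5,0.7,1.8,0.9
PCB-170,PCB,none,serum,ng/g lipid,lipid,TRUE,100,2.8,2.2,0.9,1.8,2.8,4.2,9.4,6.3
PCB-172,PCB,none,serum,ng/g lipid,lipid,TRUE,34,2.2,3.0,,,,0.5,1.2,0.9
PCB-177,PCB,none,serum,ng/g lipid,lipid,TRUE,61,4.0,3.1,,,0.5,0.7,2.1,1.3
PCB-178,PCB,none,serum,ng/g lipid,lipid,TRUE,52,3.3,3.2,,,0.4,0.7,1.8,1.2
PCB-183,PCB,none,serum,ng/g lipid,lipid,TRUE,87,0.8,3.0,,0.6,1.0,1.4,2.8,1.7
PCB-187,PCB,none,serum,ng/g lipid,lipid,TRUE,98,2.1,2.3,0.7,1.5,2.1,3.3,7.1,4.6
PCB-194,PCB,none,serum,ng/g lipid,lipid,TRUE,92,1.2,2.8,,0.9,1.4,2.2,4.5,4.0
PCB-195,PCB,none,serum,ng/g lipid,lipid,TRUE,39,2.4,3.1,,,,0.6,1.1,0.6
PCB-196/203,PCB,none,serum,ng/g lipid,lipid,TRUE,96,1.6,2.3,0.5,1.1,1.6,2.5,4.8,3.3
PCB-199,PCB,none,serum,ng/g lipid,lipid,TRUE,93,1.2,2.8,,0.9,1.3,2.2,4.4,3.7
PCB-206,PCB,none,serum,ng/g lipid,lipid,TRUE,81,0.6,3.2,,0.6,0.8,1.2,2.4,2.3
PCB-209,PCB,none,serum,ng/g lipid,lipid,TRUE,35,2.2,3.0,,,,0.5,1.0,1.2
beta-HCH,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,27,1.9,2.8,,,,1.9,4.4,
HCB,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,94,6.5,1.9,,5.5,7.0,9.0,13.8,16
pp-DDT,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,52,3.3,3.2,,,1.9,3.2,6.2,
pp-DDE,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,100,71.6,1.8,31,51,67,93,182,206
Oxychlordane,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,90,4.4,2.5,,3.5,5.1,7.2,13,11
trans-Nonachlor,OC_pesticide,none,serum,ng/g lipid,lipid,TRUE,97,7.5,2.1,2.3,5.1,7.4,12,25,15
BB-153,BFR,none,serum,ng/g lipid,lipid,TRUE,85,0.9,3.7,,0.6,1.1,1.9,4.5,2.0
PBDE-28,BFR,none,serum,ng/g lipid,lipid,TRUE,81,0.8,4.0,,0.5,1.1,1.8,4.2,1.0
PBDE-47,BFR,none,serum,ng/g lipid,lipid,TRUE,100,20.1,2.7,4.9,9.7,19,35,103,19
PBDE-85,BFR,none,serum,ng/g lipid,lipid,TRUE,49,3.1,3.2,,,,1.0,3.5,
PBDE-99,BFR,none,serum,ng/g lipid,lipid,TRUE,100,4.7,2.9,1.0,2.2,4.4,8.0,33,
PBDE-100,BFR,none,serum,ng/g lipid,lipid,TRUE,99,3.8,3.0,0.9,2.0,3.4,7.9,25,3.2
PBDE-153,BFR,none,serum,ng/g lipid,lipid,TRUE,99,5.1,3.1,1.3,2.4,4.2,9.0,54,4.0
PBDE-154,BFR,none,serum,ng/g lipid,lipid,TRUE,42,2.6,3.1,,,,0.9,2.8,0.8
PFOA,PFAS,none,serum,ug/L,none,TRUE,100,5.6,1.7,2.5,3.8,5.5,7.6,13,3.6
PFOS,PFAS,none,serum,ug/L,none,TRUE,100,13.1,1.6,5.7,9.3,13,18,27,18
PFNA,PFAS,none,serum,ug/L,none,TRUE,100,0.9,1.5,0.5,0.7,0.9,1.2,1.9,0.9
PFHxS,PFAS,none,serum,ug/L,none,TRUE,100,1.5,2.0,0.5,0.9,1.6,2.4,5.0,1.6
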