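index,Pearson,Spearman,Ftest,MutualInformation,RF,GBDT,XGB,FinalRankPublished
SR1,6,9,6,16,12,5,12,7
SR2,5,8,5,20,18,15,10,11
RVI1,15,15,15,24,14,17,14,19
RVI2,7,11,7,2,23,22,16,13
NDVI,17,17,17,11,8,4,5,10
GNDVI,12,10,12,8,21,23,20,16
NDRE,10,12,10,4,22,24,24,15
EVI2,22,22,24,6,20,19,18,23
CIgreen,8,13,8,13,24,14,22,14
CIrededge,4,7,4,15,16,10,9,6
MTCI,1,2,1,3,4,8,6,1
mND705,13,4,13,9,5,3,2,4
OSAVI,19,19,21,21,9,12,7,18
MCARI,18,20,19,22,13,20,19,22
TVI,24,23,18,12,2,2,3,12
MSR,16,16,16,23,17,18,23,21
MCAVI,23,18,20,18,15,21,21,24
SAVI1,21,21,23,7,19,16,17,20
SAVI2,2,5,2,17,11,11,15,5
Ndchi,3,3,3,5,3,7,4,2
NDSI,11,14,11,1,7,13,11,9
Mrer,14,1,14,10,1,1,1,3
REP,9,6,9,19,10,6,8,8
DDN,20,24,22,14,6,9,13,17
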