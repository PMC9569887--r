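class_code,long_name,headgroup,base_c,base_h,base_n,base_o,base_p,channels,adducts
CER,ceramide,sphingoid base,0,1,1,3,0,positive;negative,M+H;M-H
SM,sphingomyelin,phosphocholine (sphingoid),5,13,2,6,1,positive;negative,M+H;M-H
PC,phosphatidylcholine,phosphocholine,8,16,1,8,1,positive;negative,M+H;M-H
PC-O,ether phosphatidylcholine,phosphocholine (ether),8,18,1,7,1,positive,M+H
PE,phosphatidylethanolamine,phosphoethanolamine,5,10,1,8,1,positive;negative,M+H;M-H
PE-O,phosphatidylethanolamine plasmalogen (O-),phosphoethanolamine (ether),5,12,1,7,1,negative,M-H
PE-P,phosphatidylethanolamine plasmalogen (P-),phosphoethanolamine (vinyl ether),5,10,1,7,1,negative,M-H
LPC,lyso-phosphatidylcholine,phosphocholine,8,18,1,7,1,positive,M+H
LPE,lyso-phosphatidylethanolamine,phosphoethanolamine,5,12,1,7,1,negative,M-H
PG,phosphatidylglycerol,phosphoglycerol,6,11,0,10,1,negative,M-H
PI,phosphatidylinositol,phosphoinositol,9,15,0,13,1,negative,M-H
PS,phosphatidylserine,phosphoserine,6,10,1,10,1,negative,M-H
TG,triglyceride,glycerol,3,2,0,6,0,positive,M+NH4
DG,diglyceride,glycerol,3,4,0,5,0,positive,M+NH4
CE,cholesteryl ester,cholesterol,27,44,0,2,0,positive,M+NH4
CHOL,cholesterol,cholesterol,27,46,0,1,0,positive,M+H
FA,fatty acid,carboxylate,0,0,0,2,0,negative_cid,M-H
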