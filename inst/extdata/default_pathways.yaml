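NOTCH:
- NOTCH1
- NOTCH2
- NOTCH3
- FAT1
- EP300
- CREBBP
p53:
- TP53
- MDM2
cell_cycle:
- CDKN2A
- CCND1
- CDK4
- RB1
SWI_SNF:
- ARID2
- PBRM1
- SMARCA4
Hippo:
- FAT1
- AJUBA
- LATS1
- LATS2
- YAP1
stress:
- CASP8
- CHUK
- NFE2L2
MAPK_PI3K:
- HRAS
- KRAS
- PIK3CA
- PTEN
- MTOR
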