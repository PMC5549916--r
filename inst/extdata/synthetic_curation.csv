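mirna,mrna,mirna_regulation,role,reference
hsa-miR-21,TGFBR2,up,oncogenic,db:sourceA
hsa-miR-21,TGFBR2,up,oncogenic,review:sourceD
hsa-miR-21,PDCD4,up,oncogenic,db:sourceB
hsa-miR-21,TPM1,up,oncogenic,db:sourceC
hsa-miR-10b,HOXD10,up,metastasis-promoting,db:sourceA
hsa-miR-10b,HOXD10,up,metastasis-promoting,review:sourceE
hsa-miR-10b,KLF4,up,metastasis-promoting,db:sourceC
hsa-miR-96,FOXO1,up,oncogenic,review:sourceD
hsa-miR-101,STMN1,down,tumor-suppressive,db:sourceA
hsa-miR-101,MCL1,down,tumor-suppressive,db:sourceB
hsa-miR-101,MCL1,down,tumor-suppressive,review:sourceF
hsa-miR-145,ERBB2,down,tumor-suppressive,db:sourceA
hsa-miR-200c,ZEB1,down,tumor-suppressive,db:sourceC
hsa-miR-200c,ZEB2,down,tumor-suppressive,db:sourceC
hsa-miR-21,SERPINB5,up,oncogenic,review:sourceG
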