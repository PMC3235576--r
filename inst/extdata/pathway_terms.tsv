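term_id	term_name	genes
FX:0000100	immune system process	TNF;IL8;CR1;CLU;CCR2;PICALM;CHRNB2
FX:0000200	vesicle-mediated transport	PICALM;SORL1;APOE;BIN1;LDLR;CLU
FX:0000300	cellular membrane organization	SORL1;APOE;PICALM;BIN1;LDLR
FX:0000400	alcohol metabolic process	CHRNB2;SORL1;APOE;TNF;LDLR
FX:0000600	lipid transport	SORL1;APOE;LDLR;CLU;TNF
FX:0000450	steroid metabolic process	SORL1;APOE;TNF;LDLR
FX:0000470	cholesterol metabolic process	APOE;CLU;LDLR;SORL1
FX:0000500	cell death/apoptosis	APOE;TNF;CLU
FX:0000700	cell migration	IL8;APOE;TNF
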