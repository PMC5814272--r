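allele	strong_peptide	weak_peptide	strong_ic50	weak_ic50
HLA-A*01:01	LNRTKAVAD	VLQKEMREQ	1.6053	30054.5044
HLA-A*02:01	YHFTDQPQR	VLEVKHKSP	1.7739	38320.1811
HLA-B*07:02	CNFHYDADQ	WQEPLICET	1.722	35722.057
HLA-B*08:01	QQSPSTHKW	CKKTCPGQK	2.4366	33428.44
HLA-C*07:01	LCLDLIHLS	EWHTSDRAF	1.5698	29592.0043
HLA-C*07:02	TYREVDSWK	AIGMICRAI	1.7181	33124.4053
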