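gene	match	value
KRAS	protein	p.G12*
KRAS	protein	p.G13*
KRAS	protein	p.Q61*
NRAS	protein	p.G12*
NRAS	protein	p.Q61*
HRAS	protein	p.G12*
HRAS	protein	p.Q61*
BRAF	protein	p.V600*
EGFR	protein	p.L858R
EGFR	protein	p.T790M
EGFR	protein	p.G719*
ERBB2	protein	p.V777*
MET	protein	p.Y1003*
MAP2K1	protein	p.K57*
RIT1	protein	p.M90*
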