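source	herb	n
tcm_taiwan	HE	29
tcm_taiwan	RC	44
tcm_taiwan	RMO	38
tcm_taiwan	RAS	56
tcm_taiwan	CPC	7
tcm_taiwan	RA	29
tcmsp	HE	130
tcmsp	RC	78
tcmsp	RMO	174
tcmsp	RAS	125
tcmsp	CPC	58
tcmsp	RA	81
literature	HE	15
literature	RC	1
literature	RMO	5
literature	RAS	5
literature	CPC	14
literature	RA	5
literature	EXD	1
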