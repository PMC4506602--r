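herb	n_compounds	n_lipinski	pct_lipinski	n_ob_dl	pct_ob_dl	n_all	pct_all
HE	150	75	50.0	23	15.3	17	11.3
RC	104	29	27.9	7	6.7	4	3.8
RMO	189	125	66.1	20	10.6	12	6.3
RAS	173	131	75.7	5	2.9	3	1.7
CPC	63	43	68.3	28	44.4	19	30.2
RA	81	45	55.6	15	18.5	11	13.6
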