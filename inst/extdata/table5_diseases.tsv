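set_name	n_genes	pct_genes	p_value
Cancer	384	14.5	9.4E-28
Cardiovascular	342	12.9	2.8E-25
Aging	79	3.0	8.7E-17
Reproduction	133	5.0	1.3E-11
Renal	100	3.8	2.5E-10
Neurological	247	9.3	1.9E-7
Infection	142	5.4	2.0E-7
Psychological	238	9.0	2.9E-7
Immune	316	11.9	1.4E-5
Hematological	70	2.6	1.4E-4
Vision	85	3.2	4.4E-4
Developmental	105	4.0	6.4E-3
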