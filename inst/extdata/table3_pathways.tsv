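set_name	xd_score	q_value	overlap	set_size
Linoleic acid metabolism	3.148	0.000	10	11
Citrate cycle (TCA cycle)	3.057	0.000	21	26
Propanoate metabolism	1.899	0.000	11	19
Arachidonic acid metabolism	1.865	0.000	17	26
PPAR signaling pathway	1.794	0.000	22	39
Tyrosine metabolism	1.475	0.001	9	17
Retinol metabolism	1.474	0.009	6	12
Bladder cancer	1.463	0.000	17	38
Ether lipid metabolism	1.370	0.002	8	16
Metabolism of xenobiotics by cytochrome P450	1.313	0.001	10	20
Adipocytokine signaling pathway	1.248	0.000	24	57
Drug metabolism: cytochrome P450	1.240	0.003	8	17
Fatty acid metabolism	1.096	0.000	12	26
Pyruvate metabolism	1.096	0.000	12	26
One carbon pool by folate	1.057	0.018	5	10
Glyoxylate and dicarboxylate metabolism	1.057	0.018	5	10
Fc epsilon RI signaling pathway	1.040	0.000	23	65
Pancreatic cancer	1.013	0.000	25	70
Steroid hormone biosynthesis	0.990	0.027	6	15
GnRH signaling pathway	0.969	0.000	32	83
Beta-Alanine metabolism	0.924	0.007	7	15
Prostate cancer	0.913	0.000	32	84
Tryptophan metabolism	0.903	0.000	12	26
Long-term depression	0.893	0.000	23	57
Toll-like receptor signaling pathway	0.883	0.000	32	90
NOD-like receptor signaling pathway	0.879	0.000	21	59
Biosynthesis of unsaturated fatty acids	0.875	0.027	5	11
Riboflavin metabolism	0.875	0.027	5	11
VEGF signaling pathway	0.872	0.000	24	62
Glycerophospholipid metabolism	0.829	0.002	13	35
Type II diabetes mellitus	0.814	0.010	13	43
Chagas disease	0.804	0.000	36	99
Selenoamino acid metabolism	0.763	0.049	6	17
Renal cell carcinoma	0.708	0.000	24	68
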