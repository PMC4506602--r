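compound	set_name
DFV ((2S)-7-hydroxy-2-(4-hydroxyphenyl)chroman-4-one)	menopause_pathway_or_disease
Kaempferol (3,5,7-trihydroxy-2-(4-hydroxyphenyl)chromen-4-one)	menopause_pathway_or_disease
Luteolin (2-(3,4-dihydroxyphenyl)-5,7-dihydroxychromen-4-one)	menopause_pathway_or_disease
Rutaecarpine	menopause_pathway_or_disease
Chryseriol (5,7-dihydroxy-2-(4-hydroxy-3-methoxyphenyl)chromen-4-one)	menopause_pathway_or_disease
Phellopterin	menopause_pathway_or_disease
Cnidilin	menopause_pathway_or_disease
Quercetin (2-(3,4-dihydroxyphenyl)-3,5,7-trihydroxychromen-4-one)	menopause_pathway_or_disease
Chelerythrine	menopause_pathway_or_disease
Berberine	menopause_pathway_or_disease
Palmatine	menopause_pathway_or_disease
Fumarine	menopause_pathway_or_disease
8-Isopentenyl-kaempferol	menopause_pathway_or_disease
Anhydroicaritin (3,5,7-trihydroxy-2-(4-methoxyphenyl)-8-(3-methylbut-2-enyl)chromen-4-one)	menopause_pathway_or_disease
Jatrorrhizine	menopause_pathway_or_disease
Stigmasterol	menopause_pathway_or_disease
Diosgenin ((3beta,25R)-spirost-5-en-3-ol)	menopause_pathway_or_disease
Beta-sitosterol	menopause_pathway_or_disease
Cycloartenol (9beta,19-Cyclo-24-lanosten-3beta-ol)	menopause_pathway_or_disease
Obacunone	menopause_pathway_or_disease
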