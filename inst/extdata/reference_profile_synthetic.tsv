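property	mean
mw	357.0
alogp	2.6
hbd	1.8
hba	5.4
rotb	5.2
tpsa	78.0
nring	2.9
heavy	25.0
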