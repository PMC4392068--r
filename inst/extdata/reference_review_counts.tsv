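variant_class	inheritance_class	reviewed_snv	reviewed_cnv	reported
autosomal_dominant	de_novo	193	49	184
autosomal_dominant	inherited	473	55	27
autosomal_recessive	de_novo	6	0	0
autosomal_recessive	inherited	424	1	52
x_linked	de_novo	36	5	31
x_linked	inherited	360	11	23
uncertain	uncertain	0	83	0
uniparental_disomy	other	NA	NA	6
mosaicism	other	NA	NA	5
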