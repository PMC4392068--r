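category	trio_inherited	trio_de_novo	proband_only
autosomal_dominant	473	193	9529
autosomal_recessive_homozygous	83	0	191
autosomal_recessive_compound_het	341	6	1071
x_linked_dominant	38	21	269
x_linked_recessive	322	15	387
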