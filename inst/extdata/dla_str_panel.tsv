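locus	chromosome	region	tuple_position	n_alleles	size_min	size_max
DLA-I-3CCA	CFA12	dla_class_I	1	14	375	393
DLA-I-4ACA	CFA12	dla_class_I	2	12	364	381
DLA-I-4BCT	CFA12	dla_class_I	3	6	277	293
DLA-1131	CFA12	dla_class_I	4	9	178	188
5ACA	CFA12	dla_class_II	1	6	339	351
5ACT	CFA12	dla_class_II	2	7	321	329
5BCA	CFA12	dla_class_II	3	6	268	288
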