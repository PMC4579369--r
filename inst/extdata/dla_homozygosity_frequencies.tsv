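disease	region	case_freq	control_freq	n_cases	n_controls
AD	dla_class_I	0.24	0.17	74	314
AD	dla_class_II	0.53	0.44	74	314
SA	dla_class_I	0.12	0.17	61	314
SA	dla_class_II	0.51	0.44	61	314
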