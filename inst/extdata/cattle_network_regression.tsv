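dataset	trait	n_full	r2_full	r2_random_mean	n_selected	r2_selected	cv_r2_mean
CHA_Ru	EFF	19	0.61	0.36	8	0.58	0.30
CHA_Ru	CH4Y	22	0.62	0.39	11	0.59	0.17
CHA_Ru	ACET_PROP	36	0.88	0.71	17	0.84	0.36
CHA_Fe	EFF	13	0.63	0.19	8	0.59	0.54
CHA_Fe	CH4Y	13	0.59	0.24	7	0.56	0.46
CHA_Fe	ACET_PROP	13	0.57	0.25	6	0.54	0.24
HOL_Ru	EFF	14	0.70	0.26	8	0.66	0.27
HOL_Ru	CH4Y	20	0.63	0.36	7	0.60	0.20
HOL_Ru	ACET_PROP	28	0.81	0.54	15	0.76	0.23
HOL_Fe	EFF	11	0.47	0.20	7	0.45	0.24
HOL_Fe	CH4Y	17	0.69	0.33	9	0.65	0.11
HOL_Fe	ACET_PROP	12	0.61	0.22	8	0.58	0.11
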