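# Mean fluorescence lifetimes (tau_m, ns) of 2-AP-labeled MiniROSE RNA with
# the conserved G15 deleted; only three labeling positions were measured.
site	condition	parameter	value	error
24	20C_free	tau_m	0.38	0.02
27	20C_free	tau_m	0.31	0.02
35	20C_free	tau_m	0.30	0.01
24	20C_bound	tau_m	0.87	0.04
27	20C_bound	tau_m	0.65	0.03
35	20C_bound	tau_m	0.47	0.03
24	45C_free	tau_m	0.48	0.03
27	45C_free	tau_m	0.39	0.02
35	45C_free	tau_m	0.28	0.01
24	45C_bound	tau_m	0.57	0.02
27	45C_bound	tau_m	0.75	0.04
35	45C_bound	tau_m	0.41	0.02
24	45C_urea_free	tau_m	1.41	0.05
27	45C_urea_free	tau_m	1.12	0.04
35	45C_urea_free	tau_m	1.09	0.04
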