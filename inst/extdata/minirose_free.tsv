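# Site-by-condition fluorescence parameters for free (ribosome-unbound)
# 2-AP-labeled MiniROSE RNA.
# parameter: tau_m = mean fluorescence lifetime (ns),
#            phi_m = mean rotational correlation time (ns),
#            kq    = bimolecular quenching constant (1e9 / M / s)
# condition: 20C, 45C, 45C_urea (45C in 7 M urea)
site	condition	parameter	value	error
6	20C	tau_m	1.06	0.05
10	20C	tau_m	1.86	0.05
24	20C	tau_m	1.69	0.08
27	20C	tau_m	1.34	0.06
35	20C	tau_m	1.82	0.01
38	20C	tau_m	0.91	0.05
41	20C	tau_m	1.22	0.05
6	45C	tau_m	0.60	0.06
10	45C	tau_m	1.88	0.04
24	45C	tau_m	2.12	0.01
27	45C	tau_m	1.32	0.02
35	45C	tau_m	1.49	0.02
38	45C	tau_m	1.01	0.03
41	45C	tau_m	1.05	0.09
6	45C_urea	tau_m	1.30	0.04
10	45C_urea	tau_m	1.65	0.05
24	45C_urea	tau_m	1.67	0.03
27	45C_urea	tau_m	1.72	0.06
35	45C_urea	tau_m	2.22	0.07
38	45C_urea	tau_m	1.90	0.03
41	45C_urea	tau_m	2.22	0.05
6	20C	phi_m	2.82	0.10
10	20C	phi_m	3.46	0.08
24	20C	phi_m	2.86	0.21
27	20C	phi_m	1.54	0.05
35	20C	phi_m	1.58	0.08
38	20C	phi_m	1.85	0.11
41	20C	phi_m	1.09	0.10
6	45C	phi_m	1.41	0.09
10	45C	phi_m	0.87	0.03
24	45C	phi_m	0.81	0.03
27	45C	phi_m	0.40	0.02
35	45C	phi_m	1.27	0.05
38	45C	phi_m	0.51	0.02
41	45C	phi_m	0.25	0.02
6	45C_urea	phi_m	0.98	0.03
10	45C_urea	phi_m	0.83	0.05
24	45C_urea	phi_m	0.63	0.03
27	45C_urea	phi_m	0.69	0.04
35	45C_urea	phi_m	0.65	0.02
38	45C_urea	phi_m	1.09	0.03
41	45C_urea	phi_m	0.62	0.04
6	20C	kq	4.7	0.3
10	20C	kq	7.0	0.4
24	20C	kq	20.4	0.9
27	20C	kq	20.3	0.5
35	20C	kq	4.2	0.2
38	20C	kq	8.9	0.4
41	20C	kq	6.8	0.3
6	45C	kq	7.5	0.4
10	45C	kq	6.8	0.3
24	45C	kq	9.7	0.2
27	45C	kq	12.6	0.4
35	45C	kq	5.0	0.3
38	45C	kq	10.7	0.5
41	45C	kq	5.5	0.4
6	45C_urea	kq	2.7	0.2
10	45C_urea	kq	2.3	0.1
24	45C_urea	kq	3.0	0.2
27	45C_urea	kq	2.9	0.2
35	45C_urea	kq	2.3	0.1
38	45C_urea	kq	2.7	0.2
41	45C_urea	kq	3.1	0.1
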