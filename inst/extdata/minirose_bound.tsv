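# Site-by-condition fluorescence parameters for ribosome-bound
# 2-AP-labeled MiniROSE RNA.  phi_m was computed with the long
# (beyond-window) rotational correlation time taken as 50 ns.
site	condition	parameter	value	error
6	20C	tau_m	1.36	0.04
10	20C	tau_m	2.00	0.07
24	20C	tau_m	1.03	0.05
27	20C	tau_m	1.10	0.05
35	20C	tau_m	1.31	0.10
38	20C	tau_m	1.95	0.03
41	20C	tau_m	1.75	0.06
6	45C	tau_m	1.04	0.03
10	45C	tau_m	1.88	0.08
24	45C	tau_m	1.66	0.04
27	45C	tau_m	1.53	0.05
35	45C	tau_m	1.47	0.05
38	45C	tau_m	1.72	0.03
41	45C	tau_m	1.65	0.04
6	20C	phi_m	28.5	1.5
10	20C	phi_m	28.8	1.1
24	20C	phi_m	31.4	1.3
27	20C	phi_m	24.3	0.9
35	20C	phi_m	19.0	1.3
38	20C	phi_m	15.6	1.4
41	20C	phi_m	25.4	1.2
6	45C	phi_m	15.6	0.9
10	45C	phi_m	14.8	1.0
24	45C	phi_m	9.7	0.8
27	45C	phi_m	13.7	1.1
35	45C	phi_m	15.3	0.6
38	45C	phi_m	22.8	1.3
41	45C	phi_m	8.7	0.3
6	20C	kq	3.8	0.2
10	20C	kq	2.7	0.1
24	20C	kq	4.4	0.2
27	20C	kq	8.9	0.3
35	20C	kq	5.7	0.2
38	20C	kq	3.1	0.2
41	20C	kq	3.0	0.1
6	45C	kq	5.2	0.3
10	45C	kq	3.3	0.2
24	45C	kq	5.9	0.5
27	45C	kq	4.8	0.2
35	45C	kq	4.2	0.3
38	45C	kq	5.9	0.4
41	45C	kq	4.6	0.3
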