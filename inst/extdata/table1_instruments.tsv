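gene	variant_id	effect_allele	other_allele	eaf	beta	ci_low	ci_high	pvalue	rcc_available
HMGCR	rs7711235	A	G	0.73	-0.038	-0.050	-0.025	5.00e-10	TRUE
HMGCR	rs3857388	T	C	0.87	-0.042	-0.054	-0.031	2.20e-11	TRUE
HMGCR	rs10515198	G	A	0.90	-0.060	-0.072	-0.048	5.99e-22	TRUE
HMGCR	rs12916	T	C	0.57	-0.073	-0.081	-0.066	7.79e-78	TRUE
HMGCR	rs12173076	T	G	0.88	-0.065	-0.076	-0.054	2.33e-27	TRUE
NPC1L1	rs217386	A	G	0.81	-0.049	-0.058	-0.039	1.92e-21	TRUE
NPC1L1	rs2073547	A	G	0.41	-0.036	-0.044	-0.029	1.20e-19	TRUE
NPC1L1	rs17655652	C	T	0.29	-0.028	-0.037	-0.019	2.18e-10	TRUE
NPC1L1	rs7791240	T	C	0.91	-0.043	-0.055	-0.030	1.84e-10	TRUE
PCSK9	rs2479394	A	G	0.71	-0.039	-0.047	-0.031	1.58e-19	TRUE
PCSK9	rs11206510	C	T	0.15	-0.083	-0.093	-0.073	2.38e-53	TRUE
PCSK9	rs2479409	A	G	0.67	-0.064	-0.072	-0.056	2.52e-50	TRUE
PCSK9	rs11591147	T	G	0.02	-0.497	-0.532	-0.462	8.58e-143	FALSE
PCSK9	rs11206514	C	A	0.39	-0.051	-0.059	-0.043	9.95e-33	TRUE
PCSK9	rs572512	C	T	0.65	-0.048	-0.057	-0.039	5.31e-26	TRUE
PCSK9	rs585131	C	T	0.18	-0.064	-0.074	-0.054	2.70e-35	TRUE
PCSK9	rs12067569	G	A	0.97	-0.089	-0.108	-0.069	1.97e-17	FALSE
PCSK9	rs10493176	G	T	0.11	-0.078	-0.098	-0.058	2.54e-14	TRUE
PCSK9	rs11583974	G	A	0.97	-0.065	-0.088	-0.042	3.95e-9	FALSE
PCSK9	rs2495477	C	T	NA	-0.064	-0.075	-0.053	7.29e-30	TRUE
LDLR	rs12983316	A	G	0.83	-0.051	-0.062	-0.041	7.44e-22	TRUE
LDLR	rs3786721	C	T	0.54	-0.047	-0.054	-0.039	2.89e-31	TRUE
LDLR	rs12052058	T	G	0.25	-0.075	-0.083	-0.067	9.66e-62	TRUE
LDLR	rs6511720	T	G	0.10	-0.221	-0.233	-0.209	1.00e-200	TRUE
LDLR	rs73015030	A	G	0.03	-0.152	-0.181	-0.123	2.62e-22	FALSE
LDLR	rs1799898	T	C	0.15	-0.033	-0.044	-0.023	1.96e-9	TRUE
LDLR	rs688	C	T	0.55	-0.054	-0.061	-0.047	1.01e-43	TRUE
LDLR	rs2738464	G	C	0.13	-0.042	-0.054	-0.030	2.73e-10	TRUE
LDLR	rs5742911	G	A	0.27	-0.061	-0.072	-0.049	4.83e-24	TRUE
LDLR	rs892114	G	A	0.77	-0.035	-0.045	-0.026	7.63e-13	TRUE
LDLR	rs7251031	T	G	0.71	-0.046	-0.055	-0.037	6.24e-23	TRUE
LDLR	rs379309	T	C	0.50	-0.031	-0.039	-0.024	1.39e-13	TRUE
CETP	rs12448528	G	A	0.77	-0.037	-0.047	-0.027	1.06e-12	TRUE
CETP	rs247616	T	C	0.29	-0.055	-0.063	-0.047	2.57e-37	TRUE
CETP	rs1864163	G	A	0.73	-0.044	-0.053	-0.035	7.97e-21	TRUE
CETP	rs9989419	G	A	0.59	-0.028	-0.035	-0.020	2.49e-12	TRUE
CETP	rs12920974	G	T	0.68	-0.032	-0.043	-0.021	2.96e-8	TRUE
CETP	rs9929488	G	C	0.70	-0.037	-0.047	-0.028	8.15e-13	TRUE
CETP	rs118146573	G	A	0.87	-0.053	-0.069	-0.038	1.02e-10	TRUE
CETP	rs289714	A	G	0.79	-0.036	-0.046	-0.025	2.85e-10	TRUE
APOB	rs4665788	C	T	0.77	-0.067	-0.075	-0.058	1.12e-52	TRUE
APOB	rs11685356	C	T	0.77	-0.052	-0.060	-0.043	1.21e-31	FALSE
APOB	rs6754295	G	T	0.26	-0.063	-0.071	-0.055	1.64e-47	TRUE
APOB	rs6725189	T	G	0.23	-0.060	-0.069	-0.052	5.63e-40	TRUE
APOB	rs533617	C	T	0.05	-0.141	-0.160	-0.121	9.63e-45	TRUE
APOB	rs3791981	G	A	0.12	-0.094	-0.107	-0.081	2.03e-41	TRUE
APOB	rs12691202	T	C	0.05	-0.097	-0.119	-0.074	8.22e-19	FALSE
APOB	rs12720842	T	C	0.98	-0.099	-0.122	-0.077	1.88e-15	FALSE
APOB	rs12720796	A	C	0.98	-0.091	-0.119	-0.063	1.68e-10	FALSE
APOB	rs1367117	G	A	0.71	-0.119	-0.126	-0.111	9.48e-183	TRUE
APOB	rs17398765	A	G	0.93	-0.092	-0.107	-0.077	3.54e-32	TRUE
APOB	rs7567653	A	G	0.04	-0.115	-0.136	-0.093	3.37e-26	FALSE
APOB	rs515135	T	C	0.22	-0.139	-0.149	-0.130	1.09e-178	TRUE
APOB	rs6756743	C	T	0.96	-0.055	-0.073	-0.037	4.97e-9	FALSE
APOB	rs113588790	C	T	0.98	-0.090	-0.118	-0.061	3.94e-9	FALSE
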