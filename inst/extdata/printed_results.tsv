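target	stratum	or	ci_low	ci_high	p_printed	fdr_p_printed
HMGCR	overall	1.42	0.29	6.99	0.668	NA
HMGCR	men	1.25	0.56	2.79	0.583	NA
HMGCR	women	0.97	0.36	2.66	0.956	NA
PCSK9	overall	1.55	0.54	4.48	0.421	0.520
PCSK9	men	2.20	1.24	3.89	0.007	0.045
PCSK9	women	0.96	0.42	2.16	0.914	0.701
CETP	overall	18.8	2.45	143.9	4.79e-4	0.006
CETP	men	2.16	0.77	6.11	0.145	0.305
CETP	women	4.31	1.19	15.6	0.026	0.112
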