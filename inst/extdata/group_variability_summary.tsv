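group	n_mirnas	maxmin_mean	maxmin_sd	maxmin_mean_plus_2sd	n_hypervariable	pct_hypervariable	cv_mean	cv_sd
C-C	417	2.6	2.9	8.3	15	3.6	0.28	0.18
C-HF	380	3.5	6.1	15.7	21	5.5	0.29	0.16
HF-C	446	3.2	4.2	11.6	25	5.6	0.32	0.20
HF-HF	440	2.2	1.6	5.5	6	1.4	0.24	0.13
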