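linearity	condition	phase	connection	mean_ab	sem_ab	mean_ba	sem_ba	t	d	p_fdr	bf10	evidence	n
linear	placebo	planning	ATL <> IC	0.57	0.03	0.61	0.04	-1.43	0.20	0.189	0.39	anecdotal H0	53
linear	placebo	planning	ATL <> IFC	0.22	0.02	0.38	0.03	-5.73	0.79	0.000	30727.69	extreme H1	53
linear	placebo	planning	IC <> IFC	0.48	0.03	0.55	0.03	-3.50	0.48	0.006	28.86	strong H1	53
linear	placebo	standby	ATL <> IC	0.57	0.03	0.62	0.04	-2.08	0.29	0.086	1.08	anecdotal H1	53
linear	placebo	standby	ATL <> IFC	0.23	0.02	0.35	0.02	-4.01	0.55	0.002	123.45	extreme H1	53
linear	placebo	standby	IC <> IFC	0.41	0.03	0.46	0.03	-1.55	0.21	0.176	0.46	anecdotal H0	53
linear	placebo	perception	ATL <> IC	0.49	0.03	0.55	0.04	-2.02	0.28	0.087	0.98	anecdotal H0	53
linear	placebo	perception	ATL <> IFC	0.43	0.03	0.49	0.04	-1.51	0.21	0.177	0.43	anecdotal H0	53
linear	placebo	perception	IC <> IFC	0.62	0.03	0.67	0.03	-1.74	0.24	0.143	0.61	anecdotal H0	53
linear	mph	planning	ATL <> IC	0.67	0.03	0.68	0.03	-0.19	0.03	0.853	0.15	moderate H0	53
linear	mph	planning	ATL <> IFC	0.37	0.03	0.44	0.03	-2.12	0.29	0.086	1.16	anecdotal H1	53
linear	mph	planning	IC <> IFC	0.45	0.03	0.43	0.04	0.51	0.07	0.691	0.17	moderate H0	53
linear	mph	standby	ATL <> IC	0.65	0.03	0.66	0.03	-0.41	0.06	0.723	0.16	moderate H0	53
linear	mph	standby	ATL <> IFC	0.28	0.02	0.35	0.03	-2.20	0.30	0.082	1.37	anecdotal H1	53
linear	mph	standby	IC <> IFC	0.32	0.03	0.37	0.03	-1.57	0.22	0.176	0.47	anecdotal H0	53
linear	mph	perception	ATL <> IC	0.49	0.03	0.57	0.03	-2.53	0.35	0.044	2.66	anecdotal H1	53
linear	mph	perception	ATL <> IFC	0.38	0.02	0.51	0.03	-3.41	0.47	0.006	22.64	strong H1	53
linear	mph	perception	IC <> IFC	0.55	0.03	0.65	0.04	-2.96	0.41	0.017	7.23	moderate H1	53
nonlinear	placebo	planning	ATL <> IC	0.33	0.03	0.40	0.03	-1.73	0.24	0.146	0.6	anecdotal H0	53
nonlinear	placebo	planning	ATL <> IFC	0.26	0.03	0.17	0.02	2.31	0.32	0.057	1.7	anecdotal H1	53
nonlinear	placebo	planning	IC <> IFC	0.37	0.03	0.21	0.02	4.84	0.67	0.000	1615.28	extreme H1	53
nonlinear	placebo	standby	ATL <> IC	0.35	0.03	0.38	0.03	-0.69	0.09	0.558	0.19	moderate H0	53
nonlinear	placebo	standby	ATL <> IFC	0.24	0.02	0.17	0.02	2.21	0.30	0.057	1.39	anecdotal H1	53
nonlinear	placebo	standby	IC <> IFC	0.39	0.03	0.23	0.03	3.77	0.52	0.001	61.87	very strong H1	53
nonlinear	placebo	perception	ATL <> IC	0.40	0.04	0.35	0.03	1.14	0.16	0.335	0.28	moderate H0	53
nonlinear	placebo	perception	ATL <> IFC	0.36	0.03	0.37	0.03	-0.30	0.04	0.807	0.16	moderate H0	53
nonlinear	placebo	perception	IC <> IFC	0.50	0.03	0.47	0.04	0.85	0.12	0.478	0.21	moderate H0	53
nonlinear	mph	planning	ATL <> IC	0.43	0.03	0.48	0.04	-1.24	0.17	0.311	0.31	moderate H0	53
nonlinear	mph	planning	ATL <> IFC	0.42	0.03	0.24	0.02	5.23	0.72	0.000	5724.84	extreme H1	53
nonlinear	mph	planning	IC <> IFC	0.45	0.04	0.29	0.03	3.46	0.48	0.003	26.12	strong H1	53
nonlinear	mph	standby	ATL <> IC	0.39	0.03	0.48	0.04	-2.21	0.30	0.057	1.4	anecdotal H1	53
nonlinear	mph	standby	ATL <> IFC	0.36	0.03	0.16	0.02	5.86	0.81	0.000	47935.7	extreme H1	53
nonlinear	mph	standby	IC <> IFC	0.35	0.03	0.18	0.02	5.47	0.75	0.000	12635.6	extreme H1	53
nonlinear	mph	perception	ATL <> IC	0.41	0.04	0.46	0.03	-1.23	0.17	0.311	0.3	moderate H0	53
nonlinear	mph	perception	ATL <> IFC	0.36	0.03	0.36	0.03	0.07	0.01	0.948	0.15	moderate H0	53
nonlinear	mph	perception	IC <> IFC	0.55	0.03	0.46	0.03	2.22	0.31	0.057	1.43	anecdotal H1	53
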