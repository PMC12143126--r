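measure	mean_placebo	sem_placebo	mean_mph	sem_mph	t	d	p	n
rt	293.24	7.03	276.69	6.51	-3.902	0.531	0.001	54
accuracy	0.97	0.00	0.98	0.00	1.735	0.236	0.089	54
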