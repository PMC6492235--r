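model	x	ii_mean	ii_sd	d0_mean	d0_sd	sd1_mean	sd1_sd	dt	dt_high	dt_low	flag
CAT+GTR+G	0.025	3.50	0.03	2.99	0.22	2.07	0.22	0.91	1.31	0.46	ok
CAT+GTR+G	0.05	3.54	0.05	3.22	0.19	2.19	0.24	1.02	1.44	0.60	ok
CAT+GTR+G	0.10	3.65	0.10	3.29	0.26	2.22	0.23	1.07	1.56	0.57	ok
CAT+GTR+G	0.20	4.00	0.19	3.61	0.32	2.32	0.25	1.32	1.87	0.70	meansoff
CAT+GTR+G	0.40	4.82	0.38	4.55	0.44	2.50	0.28	1.74	2.48	1.01	meansoff
LG+G	0.025	3.51	0.02	3.36	0.09	2.61	0.15	0.75	0.98	0.51	ok
LG+G	0.05	3.53	0.05	3.37	0.11	2.62	0.15	0.75	1.00	0.48	ok
LG+G	0.10	3.60	0.09	3.45	0.13	2.67	0.16	0.79	1.07	0.50	ok
LG+G	0.20	3.75	0.14	3.62	0.16	2.74	0.18	0.88	1.21	0.53	ok
LG+G	0.40	3.92	0.21	3.79	0.21	2.83	0.21	0.96	1.37	0.53	ok
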