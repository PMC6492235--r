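model	x	ii_mean	ii_sd	d0_mean	d0_sd	sd1_mean	sd1_sd	dt	dt_high	dt_low	flag
CAT+GTR+G	3.2	3.25	0.05	2.80	0.16	1.99	0.19	0.80	1.17	0.44	ok
CAT+GTR+G	3.5	3.54	0.05	3.22	0.19	2.19	0.24	1.02	1.44	0.60	ok
CAT+GTR+G	3.8	3.83	0.05	3.44	0.21	2.27	0.24	1.17	1.62	0.71	ok
CAT+GTR+G	4.1	4.12	0.05	3.71	0.23	2.38	0.25	1.32	1.81	0.84	ok
CAT+GTR+G-nocal11	3.5	3.52	0.05	3.00	0.29	1.78	0.25	1.22	1.77	0.66	ok
CAT+GTR+G-nocal11	3.8	3.81	0.05	3.15	0.29	1.77	0.25	1.37	1.93	0.81	ok
LG+G	3.2	3.27	0.05	3.19	0.08	2.51	0.13	0.68	0.89	0.46	ok
LG+G	3.5	3.53	0.05	3.40	0.09	2.64	0.15	0.77	1.00	0.53	ok
LG+G	3.8	3.81	0.05	3.64	0.12	2.77	0.17	0.88	1.16	0.58	ok
LG+G	4.1	4.10	0.05	3.91	0.14	2.90	0.19	1.01	1.34	0.68	ok
LG+G-nocal11	3.5	3.49	0.05	3.18	0.19	2.30	0.20	0.87	1.26	0.48	ok
LG+G-nocal11	3.8	3.79	0.05	3.52	0.19	2.55	0.22	1.38	0.97	0.55	transposed
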