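gene	chromosome	n_minor	quality	caucasian_or	caucasian_lo	caucasian_hi	asian_or	asian_lo	asian_hi	all_or	all_lo	all_hi	ci_hi_alt	discrepancy
APOE	19	4167	AAA	3.77	3.29	4.32	3.99	2.86	5.57	3.61	3.2	4.08	NA	FALSE
CLU	8	53712	AAA	0.87	0.85	0.9	NA	NA	NA	0.88	0.86	0.91	NA	FALSE
PICALM	11	44358	AAA	0.89	0.86	0.92	NA	NA	NA	0.9	0.86	0.93	NA	FALSE
EXOC3L2	19	13519	AAA	1.17	1.12	1.23	NA	NA	NA	1.17	1.12	1.23	NA	FALSE
BIN1	2	24713	AAA	1.14	1.08	1.21	NA	NA	NA	1.14	1.08	1.21	NA	FALSE
CR1	1	18779	AAA	1.14	1.08	1.2	NA	NA	NA	1.16	1.09	1.22	NA	FALSE
SORL1	11	1734	AAA	1.07	1	1.15	1.3	1.13	1.5	1.1	1.02	1.17	NA	FALSE
TNK1	17	3538	AAA	0.84	0.76	0.93	NA	NA	NA	0.84	0.76	0.93	NA	FALSE
IL8	4	1157	AAA	1.26	1.01	1.58	NA	NA	NA	1.26	1.01	1.58	NA	FALSE
LDLR	19	1228	AAA	0.85	0.72	0.89	NA	NA	NA	0.85	0.72	0.89	0.99	TRUE
CST3	20	1203	AAA	1.28	1.04	1.56	NA	NA	NA	1.23	1.03	1.48	NA	FALSE
CHRNB2	1	227	BAA	0.69	0.51	0.95	NA	NA	NA	0.67	0.5	0.9	NA	FALSE
SORCS1	10	567	BAA	1.34	1.09	1.65	NA	NA	NA	1.34	1.09	1.65	NA	FALSE
TNF	6	301	BAA	NA	NA	NA	1.37	1.05	1.79	1.35	1.39	1.77	NA	TRUE
CCR2	3	308	BAA	0.73	0.56	0.97	NA	NA	NA	0.73	0.56	0.97	NA	FALSE
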