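variable	patient_mean	patient_sd	patient_n	control_mean	control_sd	control_n	printed_p	reproducible
Age (years)	69.7	8.45	23	68.75	7.43	20	0.701	FALSE
Years of education	8.17	2.44	23	9.55	2.2	20	0.060	TRUE
MMSE	23.35	4.38	23	28.1	0.97	20	<0.001	TRUE
MoCA	18.87	5.11	23	24.65	1.84	20	<0.001	TRUE
CAMCOG-C total	75.91	8.39	23	93	4.05	20	<0.001	TRUE
CAMCOG-C orientation	8.7	1.61	23	9.9	0.31	20	<0.001	FALSE
CAMCOG-C language	22.3	2.89	23	27.15	1.73	20	<0.001	TRUE
CAMCOG-C memory	19.09	3.66	23	22.1	2.22	20	0.003	TRUE
CAMCOG-C attention	4.65	1.67	23	6.5	0.76	20	<0.001	TRUE
CAMCOG-C praxis	7.52	1.62	23	10.95	1	20	<0.001	TRUE
CAMCOG-C calculation	1.83	0.39	23	2	0	20	0.052	FALSE
CAMCOG-C abstraction	5.29	1.32	23	6.51	0.76	20	0.010	FALSE
CAMCOG-C perception	6.83	1.34	23	7.09	1.33	20	0.012	FALSE
ADL	24.57	9.4	23	20.25	0.72	20	0.047	TRUE
GDS	5.3	2.84	23	3.95	2.8	20	0.124	FALSE
CDR	0.717	0.47	23	0	0	20	<0.001	TRUE
Word immediate recall	3.74	0.86	23	4.55	1.54	20	0.036	TRUE
Word delayed recall	4.04	1.22	23	4.85	1.57	20	0.065	FALSE
Stroop (dot)	37.56	13.49	23	23.45	9.75	20	<0.001	TRUE
Stroop (characters)	47.86	23.29	23	31.05	9.61	20	0.050	FALSE
Stroop (color)	68.65	25.34	23	45.6	11.41	20	0.001	TRUE
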