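variable	mean_1	sd_1	n_1	mean_2	sd_2	n_2	published_t	published_g
parental_csl_proficiency	6.81	0.54	16	2.74	1.29	23	13.54	4.04
age_years	28.50	7.13	16	27.09	5.87	23	0.65	0.21
education_years	14.13	2.31	16	15.09	1.41	23	-1.49	-0.49
subjective_social_status_childhood	3.88	2.58	16	4.35	1.97	23	-0.62	-0.20
father_education_years	7.19	3.04	16	10.39	2.84	23	-3.33	-1.07
mother_education_years	6.56	3.14	16	8.52	2.73	23	-2.02	-0.65
csl_comprehension	6.06	0.93	16	6.17	0.89	23	-0.38	-0.12
csl_production	5.75	1.00	16	5.87	1.10	23	-0.35	-0.11
lipreading_acquaintances	2.81	1.11	16	3.17	1.19	23	-0.97	-0.31
lipreading_strangers	1.88	0.81	16	1.87	0.97	23	0.02	0.01
arhq_total	2.59	0.68	16	2.84	0.52	23	-1.25	-0.41
arhq_item26_reading_speed	2.38	1.36	16	3.13	1.01	23	-1.89	-0.62
arhq_item29_writing_skills	2.25	1.00	16	3.17	0.94	23	-2.91	-0.93
arhq_item40_reading_comprehension	2.44	0.81	16	2.70	0.97	23	-0.90	-0.28
framewise_displacement_mm	0.12	0.04	16	0.11	0.04	23	0.77	NA
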