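genus	method	SW0	SW4	SW8	SWO4	SWO8	SWOB4	SWOB8
Colwellia	Kaiju	3.96	4.94	3.86	4.57	10.87	1.73	0.60
Colwellia	KaijuMAR	17.78	8.46	5.18	4.90	13.63	1.86	1.08
Colwellia	Kraken2	8.32	9.97	6.26	4.94	10.83	1.40	0.61
Colwellia	Bracken	6.73	8.16	5.34	4.33	10.05	1.33	0.54
Colwellia	Amplicon	6.45	4.63	3.53	2.75	9.91	1.07	1.80
Colwellia	Quantification	NA	NA	7.35	NA	13.83	0.85	0.34
Cycloclasticus	Kaiju	0.13	10.05	8.81	1.10	2.12	1.82	13.36
Cycloclasticus	KaijuMAR	0.25	23.20	16.69	1.75	3.99	2.66	25.33
Cycloclasticus	Kraken2	0.18	1.90	1.48	0.14	0.23	0.21	4.88
Cycloclasticus	Bracken	0.14	1.55	1.25	0.12	0.21	0.20	4.34
Cycloclasticus	Amplicon	0.05	2.13	1.90	0.25	0.46	0.59	7.74
Cycloclasticus	Quantification	NA	NA	0.25	NA	0.01	0.14	7.60
Pseudomonas	Kaiju	1.96	1.23	1.97	9.64	6.42	38.41	25.39
Pseudomonas	KaijuMAR	0.48	0.94	2.24	8.59	9.44	39.03	13.88
Pseudomonas	Kraken2	3.02	5.68	5.37	13.64	13.06	50.54	34.33
Pseudomonas	Bracken	2.71	4.74	4.83	12.21	11.97	48.14	31.65
Pseudomonas	Amplicon	0.26	0.20	0.25	0.78	0.24	10.76	3.70
Pseudomonas	Quantification	NA	NA	2.59	NA	5.08	9.52	9.25
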