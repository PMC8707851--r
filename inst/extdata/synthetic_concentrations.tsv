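treatment	time_months	analyte	concentration	unit
SWOs	0	THC	100	mg/L
SWOs	4	THC	92	mg/L
SWOs	8	THC	71	mg/L
SWO	0	THC	100	mg/L
SWO	4	THC	91	mg/L
SWO	8	THC	70	mg/L
SWOB	0	THC	100	mg/L
SWOB	4	THC	90	mg/L
SWOB	8	THC	59	mg/L
SWOs	0	PAH16	10	mg/L
SWOs	4	PAH16	4.7	mg/L
SWOs	8	PAH16	3.5	mg/L
SWO	0	PAH16	10	mg/L
SWO	4	PAH16	4.2	mg/L
SWO	8	PAH16	3.2	mg/L
SWOB	0	PAH16	10	mg/L
SWOB	4	PAH16	2.9	mg/L
SWOB	8	PAH16	1.5	mg/L
SWOB	0	naphthalene	1.2	mg/L
SWOB	4	naphthalene	0.006	mg/L
SWOB	8	naphthalene	0.002	mg/L
SWOB	0	n-C17	2.4	mg/L
SWOB	4	n-C17	1.6	mg/L
SWOB	8	n-C17	0.7	mg/L
SWOB	0	pristane	1.9	mg/L
SWOB	4	pristane	1.8	mg/L
SWOB	8	pristane	1.5	mg/L
SWOB	0	n-C18	2.1	mg/L
SWOB	4	n-C18	1.3	mg/L
SWOB	8	n-C18	0.6	mg/L
SWOB	0	phytane	1.7	mg/L
SWOB	4	phytane	1.6	mg/L
SWOB	8	phytane	1.4	mg/L
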