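rbp	pwm_id	pos	A	C	G	U
CPEB1	CPEB1_1	1	0.05	0.05	0.05	0.85
CPEB1	CPEB1_1	2	0.05	0.05	0.05	0.85
CPEB1	CPEB1_1	3	0.05	0.05	0.05	0.85
CPEB1	CPEB1_1	4	0.85	0.05	0.05	0.05
CPEB1	CPEB1_1	5	0.05	0.05	0.05	0.85
CPEB1	CPEB1_1	6	0.85	0.05	0.05	0.05
ELAVL1	ELAVL1_1	1	0.10	0.05	0.05	0.80
ELAVL1	ELAVL1_1	2	0.10	0.05	0.05	0.80
ELAVL1	ELAVL1_1	3	0.10	0.05	0.05	0.80
ELAVL1	ELAVL1_1	4	0.10	0.05	0.05	0.80
ELAVL1	ELAVL1_1	5	0.80	0.05	0.05	0.10
ELAVL1	ELAVL1_2	1	0.05	0.05	0.05	0.85
ELAVL1	ELAVL1_2	2	0.05	0.05	0.05	0.85
ELAVL1	ELAVL1_2	3	0.05	0.05	0.05	0.85
ELAVL1	ELAVL1_2	4	0.05	0.05	0.05	0.85
ELAVL1	ELAVL1_2	5	0.05	0.05	0.05	0.85
PUM1	PUM1_1	1	0.02	0.02	0.02	0.94
PUM1	PUM1_1	2	0.02	0.02	0.94	0.02
PUM1	PUM1_1	3	0.94	0.02	0.02	0.02
PUM1	PUM1_1	4	0.02	0.02	0.02	0.94
PUM1	PUM1_1	5	0.94	0.02	0.02	0.02
PUM1	PUM1_1	6	0.02	0.02	0.02	0.94
PUM1	PUM1_1	7	0.94	0.02	0.02	0.02
PUM1	PUM1_1	8	0.02	0.02	0.02	0.94
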