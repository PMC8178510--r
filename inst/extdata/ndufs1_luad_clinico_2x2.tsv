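characteristic	level	high	low	numerator_level
Age	<65	12	11	NA
Age	>=65	8	8	NA
Sex	Female	7	9	Male
Sex	Male	13	10	Male
Stage	I+II	17	11	NA
Stage	III	3	8	NA
T stage	T1+T2	16	14	NA
T stage	T3+T4	4	5	NA
N stage	N0	16	8	NA
N stage	N1+N2+N3	4	11	NA
Differentiation	Poorly	4	10	NA
Differentiation	Well/moderate	16	9	NA
ki67	<20	12	7	NA
ki67	>=20	8	12	NA
Tumor maximum diameter	<3cm	14	7	NA
Tumor maximum diameter	>=3cm	6	12	NA
Lymphatic and vascular invasion	Negative	16	6	NA
Lymphatic and vascular invasion	Positive	4	13	NA
Nerve invasion	Negative	15	11	NA
Nerve invasion	Positive	5	8	NA
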