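entity_type	label	annotation_count	annotation_percentage	total
State	State	12584	32.20	39097
Position_Primary	Pos_Pri	11482	29.40	39097
Negation	Neg	3097	7.90	39097
Symptoms_Single	Symp_S	2770	7.10	39097
Position_Scope	Pos_SCP	2230	5.70	39097
Time	Time	1991	5.10	39097
Position_Subordinate	Pos_Sub	1076	2.80	39097
Severity_Qualitative	Sev_Qual	1043	2.70	39097
Frequency	Freq	988	2.50	39097
Condition	Cond	893	2.30	39097
Trend	Trend	719	1.80	39097
Severity_Quantitative	Sev_Quant	224	0.60	39097
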