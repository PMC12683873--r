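relation_type	label	annotation_count	annotation_percentage	total
(State/Symp_S)_Time	STi	15574	37.60	41373
(State/Pos_Sub)_Pos_Pri	SPri	12361	29.90	41373
(State/Symp_S)_Neg	SN	5185	12.50	41373
(State/Pos_Pri/Pos_Sub)_Pos_SCP	SSCP	2295	5.50	41373
(State/Symp_S)_Cond	SC	1564	3.80	41373
(State/Symp_S)_Freq	SF	1199	2.90	41373
(State)_Pos_Sub	SSub	1169	2.80	41373
(State/Symp_S)_Sev_Qual	SQual	1156	2.80	41373
(State/Symp_S)_Trend	STr	640	1.50	41373
(State/Symp_S)_Sev_Quant	SQuant	230	0.60	41373
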