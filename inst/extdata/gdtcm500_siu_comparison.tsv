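scheme	label_count	mitigates_nesting	tcm_siu_percentage	normalized_output
Gao2021	3	TRUE	45.33	FALSE
Zhang2020	13	FALSE	20.21	FALSE
Chang2021	7	FALSE	62.43	FALSE
Lee2022	3	FALSE	50.86	FALSE
Zou2022	9	FALSE	59.64	FALSE
Liu2022	4	TRUE	42.01	FALSE
Zhu2023	10	TRUE	62.52	FALSE
Ours	12	TRUE	70.76	TRUE
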