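family_id	member_id	detected	shared_in_family	not_in_control_panel	not_in_dbsnp	consequence
49	07S240	29549	29549	9451	3838	1000
694	DAD_1	28697	28697	9144	3666	899
2887	F2887_13	28978	9271	1681	404	156
2887	F2887_24	30691	NA	NA	NA	NA
3311	F3311_5	26774	8776	1686	328	100
3311	F3311_43	26468	NA	NA	NA	NA
531	I_1408	28841	28841	9022	3553	971
RUL036	RUL036_2	27060	11405	2746	776	188
RUL036	RUL036_7	27032	NA	NA	NA	NA
RUL153	RUL153_2	26908	8295	1373	197	53
RUL153	RUL153_3	27406	NA	NA	NA	NA
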