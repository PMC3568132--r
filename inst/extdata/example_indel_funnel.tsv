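family_id	member_id	detected	shared_in_family	not_in_control_panel	not_in_dbsnp	consequence
49	07S240	36189	36189	26077	24580	11387
694	DAD_1	35606	35606	25741	24204	11046
2887	F2887_13	34081	12299	5314	4650	1354
2887	F2887_24	31445	NA	NA	NA	NA
3311	F3311_5	30983	12442	4982	4340	579
3311	F3311_43	26441	NA	NA	NA	NA
531	I_1408	36131	36131	26082	24591	11352
RUL036	RUL036_2	25162	13042	5087	4398	587
RUL036	RUL036_7	25652	NA	NA	NA	NA
RUL153	RUL153_2	25698	11878	4445	3834	506
RUL153	RUL153_3	26045	NA	NA	NA	NA
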