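characteristic	level	sex	n
age_band	0-2	M	1605
age_band	0-2	F	1400
age_band	3-10	M	8954
age_band	3-10	F	8843
age_band	11-17	M	5318
age_band	11-17	F	5637
age_band	18-65	M	5985
age_band	18-65	F	8722
age_band	>65	M	1660
age_band	>65	F	2677
residence	Urban	M	14627
residence	Urban	F	17023
residence	Rural	M	8895
residence	Rural	F	10256
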