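corpus	abstracts	region_pairs	connections	recall_pct	precision_pct
original	1377	22577	3097	70	50
evaluated_extension	1828	11825	2111	67	51
predicted_jcn	12557	156741	28107	NA	NA
predicted_related_articles	8264	164555	36566	NA	NA
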