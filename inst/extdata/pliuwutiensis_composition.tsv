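region	t_percent	c_percent	a_percent	g_percent	total_bp	printed_gc_skew	printed_at_skew
genome	29.55	22.16	35.64	12.64	15969	-0.273	0.093
PCGs	30.20	23.60	34.10	12.10	11352	-0.322	0.061
CRs	26.60	21.30	42.70	9.40	703	-0.388	0.232
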