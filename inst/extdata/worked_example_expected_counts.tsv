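rsid	population	expected_count
rs2145402	CHB	1.1
rs2145402	CHD	0.4
rs2145402	JPT	0.5
rs2145402	CEU	11.6
rs2145402	TSI	8.2
rs2145402	ASW	1.0
rs2145402	LWK	0.0
rs2145402	MKK	0.1
rs2145402	YRI	0.1
rs2145402	GIH	4.8
rs2145402	MEX	6.6
rs4915931	CHB	0.2
rs4915931	CHD	0.1
rs4915931	JPT	0.2
rs4915931	CEU	8.8
rs4915931	TSI	4.2
rs4915931	ASW	2.5
rs4915931	LWK	1.3
rs4915931	MKK	0.3
rs4915931	YRI	2.5
rs4915931	GIH	4.1
rs4915931	MEX	2.5
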