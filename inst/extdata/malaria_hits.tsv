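variant_id	gene	p_value	intergenic
atp2b4_snp1	ATP2B4	6.1e-9	FALSE
atp2b4_snp2	ATP2B4	1.5e-8	FALSE
atp2b4_snp3	ATP2B4	2.1e-8	FALSE
atp2b4_snp4	ATP2B4	5.1e-8	FALSE
atp2b4_snp5	ATP2B4	3.4e-8	FALSE
rs2334880	MARVELD3	3.9e-8	TRUE
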