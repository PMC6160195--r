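method	chrom	start	end	size_mb	n_genes	n_snps
ed	Chr05	53667767	93840115	40.17	124	3238
ed	Chr05	100693328	103396658	2.70	8	37
ed	Chr05	132573706	169821807	37.25	138	891
ed	Chr10	11722320	20005690	8.28	64	961
ed	Chr10	53805574	57945748	4.14	20	341
ed	Chr10	191899653	196817467	4.92	68	601
ed	Chr10	210028131	211321646	1.29	15	199
snp_index	Chr10	12479910	20005690	7.53	52	912
snp_index	Chr10	54672471	56593567	1.92	6	226
snp_index	Chr10	192166533	196817467	4.65	68	536
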