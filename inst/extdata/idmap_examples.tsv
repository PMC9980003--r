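organism	alias	canonical	id_type	status
dm	wg	FBgn0284084	mod_primary	current
dm	FBgn0284084	wg	symbol	current
hs	WNT1	HGNC:12774	mod_primary	current
hs	HGNC:12774	WNT1	symbol	current
mm	Wnt1	MGI:98953	mod_primary	current
mm	MGI:98953	Wnt1	symbol	current
ce	cwn-1	WBGene00000857	mod_primary	current
ce	WBGene00000857	cwn-1	symbol	current
dr	wnt1	ZDB-GENE-980526-526	mod_primary	current
dr	ZDB-GENE-980526-526	wnt1	symbol	current
rn	Wnt1	RGD:1597195	mod_primary	current
rn	RGD:1597195	Wnt1	symbol	current
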