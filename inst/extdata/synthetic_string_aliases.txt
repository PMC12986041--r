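#string_protein_id	alias	source
9606.ENSP00000001001	DDR1	HGNC
9606.ENSP00000001002	DDR2	HGNC
9606.ENSP00000001003	COL1A1	HGNC
9606.ENSP00000001004	COL1A2	HGNC
9606.ENSP00000001005	COL3A1	HGNC
9606.ENSP00000001006	COL5A1	HGNC
9606.ENSP00000001007	COL5A2	HGNC
9606.ENSP00000001008	COL11A1	HGNC
9606.ENSP00000001009	FN1	HGNC
9606.ENSP00000001010	MMP1	HGNC
9606.ENSP00000001011	MMP2	HGNC
9606.ENSP00000001012	MMP7	HGNC
9606.ENSP00000001013	MMP9	HGNC
9606.ENSP00000001014	MMP11	HGNC
9606.ENSP00000001001	CD167a	Ensembl_gene
9606.ENSP00000001002	TKT	Ensembl_gene
9606.ENSP00000009999	ACTB	HGNC
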