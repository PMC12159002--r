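gene	population	phenotype	source	pct
CYP2B6	AFR	Normal Metabolizer	PGKB	33.4
CYP2B6	AFR	Intermediate Metabolizer	PGKB	46.6
CYP2B6	AFR	Poor Metabolizer	PGKB	15.7
CYP2B6	AFR	Rapid Metabolizer	PGKB	1.2
CYP2B6	AFR	Ultrarapid Metabolizer	PGKB	0
CYP2B6	AFR	Indeterminate	PGKB	3.1
CYP2B6	LAT	Normal Metabolizer	PGKB	33.6
CYP2B6	LAT	Intermediate Metabolizer	PGKB	42.2
CYP2B6	LAT	Poor Metabolizer	PGKB	9.5
CYP2B6	LAT	Rapid Metabolizer	PGKB	12.3
CYP2B6	LAT	Ultrarapid Metabolizer	PGKB	1.1
CYP2B6	LAT	Indeterminate	PGKB	1.4
CYP2B6	EAS	Normal Metabolizer	PGKB	48.6
CYP2B6	EAS	Intermediate Metabolizer	PGKB	32.6
CYP2B6	EAS	Poor Metabolizer	PGKB	4.4
CYP2B6	EAS	Rapid Metabolizer	PGKB	11.7
CYP2B6	EAS	Ultrarapid Metabolizer	PGKB	0.7
CYP2B6	EAS	Indeterminate	PGKB	2
CYP2B6	EUR	Normal Metabolizer	PGKB	43
CYP2B6	EUR	Intermediate Metabolizer	PGKB	38
CYP2B6	EUR	Poor Metabolizer	PGKB	7.4
CYP2B6	EUR	Rapid Metabolizer	PGKB	5.4
CYP2B6	EUR	Ultrarapid Metabolizer	PGKB	0.2
CYP2B6	EUR	Indeterminate	PGKB	6.1
CYP2B6	SAS	Normal Metabolizer	PGKB	42.2
CYP2B6	SAS	Intermediate Metabolizer	PGKB	36.5
CYP2B6	SAS	Poor Metabolizer	PGKB	6
CYP2B6	SAS	Rapid Metabolizer	PGKB	12.9
CYP2B6	SAS	Ultrarapid Metabolizer	PGKB	1
CYP2B6	SAS	Indeterminate	PGKB	1.5
CYP2B6	AFR	Normal Metabolizer	LIT	25.4
CYP2B6	AFR	Intermediate Metabolizer	LIT	47.7
CYP2B6	AFR	Poor Metabolizer	LIT	21.5
CYP2B6	AFR	Rapid Metabolizer	LIT	2.7
CYP2B6	AFR	Ultrarapid Metabolizer	LIT	0
CYP2B6	AFR	Indeterminate	LIT	2.2
CYP2B6	AMR	Normal Metabolizer	LIT	35.4
CYP2B6	AMR	Intermediate Metabolizer	LIT	43.5
CYP2B6	AMR	Poor Metabolizer	LIT	16.4
CYP2B6	AMR	Rapid Metabolizer	LIT	1.4
CYP2B6	AMR	Ultrarapid Metabolizer	LIT	0
CYP2B6	AMR	Indeterminate	LIT	3.1
CYP2B6	EAS	Normal Metabolizer	LIT	51.2
CYP2B6	EAS	Intermediate Metabolizer	LIT	33.1
CYP2B6	EAS	Poor Metabolizer	LIT	5.2
CYP2B6	EAS	Rapid Metabolizer	LIT	9.3
CYP2B6	EAS	Ultrarapid Metabolizer	LIT	0.4
CYP2B6	EAS	Indeterminate	LIT	0.8
CYP2B6	EUR	Normal Metabolizer	LIT	51.2
CYP2B6	EUR	Intermediate Metabolizer	LIT	35.1
CYP2B6	EUR	Poor Metabolizer	LIT	5.8
CYP2B6	EUR	Rapid Metabolizer	LIT	4.8
CYP2B6	EUR	Ultrarapid Metabolizer	LIT	0.4
CYP2B6	EUR	Indeterminate	LIT	2.8
CYP2B6	SAS	Normal Metabolizer	LIT	30.9
CYP2B6	SAS	Intermediate Metabolizer	LIT	45.4
CYP2B6	SAS	Poor Metabolizer	LIT	15.1
CYP2B6	SAS	Rapid Metabolizer	LIT	6.5
CYP2B6	SAS	Ultrarapid Metabolizer	LIT	0
CYP2B6	SAS	Indeterminate	LIT	2
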