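variant_id	tool	value
p.Phe83Leu	PolyPhen2	Possibly damaging
p.Phe83Leu	SIFT	Damaging
p.Phe83Leu	DANN	0.9955
p.Phe83Leu	PROVEAN	Damaging
p.Phe83Leu	LRT	Deleterious
p.Phe83Leu	MutationTaster	Disease-causing
p.Phe83Leu	MutationAssessor	Medium impact
p.Phe83Leu	FATHMM	Damaging
p.Phe83Leu	FATHMM-MKL	Damaging
p.Phe83Leu	M-CAP	Damaging
p.Phe83Leu	CADD	24.9
p.Phe83Leu	MetaSVM	Damaging
p.Phe83Leu	MetaLR	Damaging
p.Phe83Leu	PhyloP20way	1.199000
p.Phe83Leu	PhyloP100way	8.735000
p.Phe83Leu	GERP_RS	5.03
p.Gly187Glu	PolyPhen2	Probably damaging
p.Gly187Glu	SIFT	Damaging
p.Gly187Glu	DANN	0.9979
p.Gly187Glu	PROVEAN	Damaging
p.Gly187Glu	LRT	Deleterious
p.Gly187Glu	MutationTaster	Disease-causing
p.Gly187Glu	MutationAssessor	Medium impact
p.Gly187Glu	FATHMM	Damaging
p.Gly187Glu	FATHMM-MKL	Damaging
p.Gly187Glu	M-CAP	Damaging
p.Gly187Glu	CADD	32
p.Gly187Glu	MetaSVM	Damaging
p.Gly187Glu	MetaLR	Damaging
p.Gly187Glu	PhyloP20way	0.807000
p.Gly187Glu	PhyloP100way	7.461000
p.Gly187Glu	GERP_RS	5.54
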