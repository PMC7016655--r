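source	pathogenic_total	pathogenic_missense	benign_count	total_classified
ClinVar_UniProt	69	52	NA	NA
HGMD	191	103	NA	NA
Varsome	NA	NA	8	93
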