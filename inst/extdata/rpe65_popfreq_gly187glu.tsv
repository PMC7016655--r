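database	allele_count	allele_number	homozygote_count
gnomAD	2	251106	0
ExAC	1	120880	0
ESP	NA	NA	NA
1000Genomes	NA	NA	NA
ABraOM	NA	NA	NA
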