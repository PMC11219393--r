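# Average per-site sequencing depth of single-locus ancestral TAS2R genes
# per species: targeted capture (tc_depth) vs public whole-genome assembly
# (wga_depth; NA where no assembly of the species is available).
species	common_name	tc_depth	wga_depth
Mmul	Rhesus macaque	1480	66
Mfus	Japanese macaque	1243	42
Mnig	Celebes crested macaque	1224	31
Panu	Anubis baboon	1372	60
Pham	Hamadryas baboon	1328	51
Epat	Patas monkey	353	52
Csab	Green monkey	1398	75
Cmit	Blue monkey	1696	83
Cpol	King colobus	1436	NA
Sent	Hanuman langur	1333	29
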