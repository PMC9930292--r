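gene	hgvs_c	hgvs_p	note
NOBOX	c.1064G>A	p.R355H	previously reported; shown to disrupt NOBOX transcriptional function
NR5A1	c.938G>A	p.R313H	previously reported in POI
MSH5	c.1051C>G	p.R351G	previously reported homozygous in a POI pedigree
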