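symbol	category	mode	omim	partner	aliases
AMH	ligand_receptor	AD	600957		
AMHR2	ligand_receptor	AD	600956		
BMP15	ligand_receptor	XLD	300247		
BMPR2	ligand_receptor	AR_AD	600799		
FSHR	ligand_receptor	AR_AD	136435		
GDF9	ligand_receptor	AR	601918		
PGRMC1	ligand_receptor	XLD	300435		
KHDRBS1	ligand_receptor	AD	602489		
ERCC6-PGBD3	meiosis	AD	609413		CSB-PGBD3
HFM1	meiosis	AR	615684		
MSH4	meiosis	AR	602105	MSH5	
MSH5	meiosis	AR	603382	MSH4	
SPIDR	meiosis	AR	615384		
SMC1B	meiosis	AR_AD	608685		
SYCE1	meiosis	AR	611486		
STAG3	meiosis	AR	608489		
MCM8	meiosis	AR	608187		
MCM9	meiosis	AR	610098		
NUP107	meiosis	AR	607617		
FIGLA	transcription_factor	AD	608697		
FOXL2	transcription_factor	AD	605597		
NOBOX	transcription_factor	AD	610934		
NR5A1	transcription_factor	AD	184757		
POLR2C	transcription_factor	AD	180663		
SOHLH1	transcription_factor	AR_AD	610224		
WT1	transcription_factor	AD	607102		
NANOS3	transcription_factor	AR	608229		
LHX8	transcription_factor	AR_AD	604425		
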