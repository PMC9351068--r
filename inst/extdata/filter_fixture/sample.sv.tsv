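SAMPLE	CHROM1	POS1	CHROM2	POS2	TYPE
FX	chr1	1500000	chr1	1509999	deletion
FX	chr1	1500000	chr1	1510000	deletion
FX	chr1	2000000	chr2	2000000	interchromosomal
FX	chr1	4200000	chr1	6000000	inversion
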