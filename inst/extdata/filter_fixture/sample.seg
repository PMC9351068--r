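SAMPLE	CHROM	START	END	MEDIAN_LOGR	DIRECTION
FX	chr1	1500001	3500000	0.15	gain
FX	chr1	1500001	3500000	0.16	gain
FX	chr1	5000001	7000000	-0.15	loss
FX	chr1	5000001	7000000	-0.16	loss
FX	chr1	5000001	5009999	0.4	gain
FX	chr1	5000001	5010000	0.4	gain
FX	chr1	1500001	9000001	0.4	gain
FX	chr1	1500001	8999999	0.4	gain
FX	chr1	500001	3000000	0.4	gain
FX	chr1	4200001	7000000	0.4	gain
FX	chr1	5000001	7000000	0.4	gain
FX	chr1	1	10000000	-0.5	loss
FX	chr2	1	10000000	0.01	cn_loh
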