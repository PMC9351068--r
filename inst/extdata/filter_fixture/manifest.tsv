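type	row	kept	rule
vcf	1	FALSE	depth
vcf	2	TRUE	NA
vcf	3	FALSE	population_af
vcf	4	TRUE	NA
vcf	5	TRUE	NA
seg	1	FALSE	logr
seg	2	TRUE	NA
seg	3	FALSE	logr
seg	4	TRUE	NA
seg	5	FALSE	min_length
seg	6	TRUE	NA
seg	7	FALSE	chrom_end_margin
seg	8	TRUE	NA
seg	9	FALSE	chrom_end_margin
seg	10	FALSE	centromere_breakpoint
seg	11	TRUE	NA
seg	12	TRUE	NA
seg	13	TRUE	NA
sv	1	FALSE	min_span
sv	2	TRUE	NA
sv	3	TRUE	NA
sv	4	FALSE	centromere_breakpoint
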