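quantity	numerator	denominator	decimals
circular_strain_pct	246	461	0
circular_species_pct	187	337	0
novel_strain_pct	384	461	0
novel_species_pct	89	337	0
rna_complete_pct	439	461	0
firmicutes_pct	278	337	1
top3_phyla_pct	317	337	0
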