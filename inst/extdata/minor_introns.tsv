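species	gene_symbol	chrom	start	end	strand	intron_class	source_flag
Dmel	lsm12a	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	sf3a1	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	stas	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	CG11839	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	Naa60	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	Nhe3	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	Phb2	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	Tsp97E	NA	NA	NA	NA	minor	named_coordinates_unknown
Dmel	minor_intron_09	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_10	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_11	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_12	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_13	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_14	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_15	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_16	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_17	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_18	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
Dmel	minor_intron_19	NA	NA	NA	NA	minor	placeholder_coordinates_unknown
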