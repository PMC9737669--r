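lncrna_id	s50_fpkm	s96_fpkm	status
LNC_001951	35512.70	11679.20	novel
Os02t0591850-01	24.79	8.94	annotated
Os03t0332600-01	46.80	16.45	annotated
Os01t0704250-00	43.22	10.33	annotated
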