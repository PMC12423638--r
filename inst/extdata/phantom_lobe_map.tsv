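code	region	lobe	hemisphere
2	left-cerebral-white-matter	WM	L
41	right-cerebral-white-matter	WM	R
4	left-lateral-ventricle	Excluded	L
43	right-lateral-ventricle	Excluded	R
24	csf	Excluded	
1001	left-frontal-cortex	Frontal	L
1002	left-parietal-cortex	Parietal	L
1003	left-temporal-cortex	Temporal	L
1004	left-occipital-cortex	Occipital	L
1005	left-insula-cortex	Insula	L
1010	left-subcortical-grey	SubCortical	L
2001	right-frontal-cortex	Frontal	R
2002	right-parietal-cortex	Parietal	R
2003	right-temporal-cortex	Temporal	R
2004	right-occipital-cortex	Occipital	R
2005	right-insula-cortex	Insula	R
2010	right-subcortical-grey	SubCortical	R
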