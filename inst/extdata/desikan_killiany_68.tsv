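region_label	hemisphere	index	region_name
lh_bankssts	L	0	left bankssts
lh_caudalanteriorcingulate	L	1	left caudalanteriorcingulate
lh_caudalmiddlefrontal	L	2	left caudalmiddlefrontal
lh_cuneus	L	3	left cuneus
lh_entorhinal	L	4	left entorhinal
lh_fusiform	L	5	left fusiform
lh_inferiorparietal	L	6	left inferiorparietal
lh_inferiortemporal	L	7	left inferiortemporal
lh_isthmuscingulate	L	8	left isthmuscingulate
lh_lateraloccipital	L	9	left lateraloccipital
lh_lateralorbitofrontal	L	10	left lateralorbitofrontal
lh_lingual	L	11	left lingual
lh_medialorbitofrontal	L	12	left medialorbitofrontal
lh_middletemporal	L	13	left middletemporal
lh_parahippocampal	L	14	left parahippocampal
lh_paracentral	L	15	left paracentral
lh_parsopercularis	L	16	left parsopercularis
lh_parsorbitalis	L	17	left parsorbitalis
lh_parstriangularis	L	18	left parstriangularis
lh_pericalcarine	L	19	left pericalcarine
lh_postcentral	L	20	left postcentral
lh_posteriorcingulate	L	21	left posteriorcingulate
lh_precentral	L	22	left precentral
lh_precuneus	L	23	left precuneus
lh_rostralanteriorcingulate	L	24	left rostralanteriorcingulate
lh_rostralmiddlefrontal	L	25	left rostralmiddlefrontal
lh_superiorfrontal	L	26	left superiorfrontal
lh_superiorparietal	L	27	left superiorparietal
lh_superiortemporal	L	28	left superiortemporal
lh_supramarginal	L	29	left supramarginal
lh_frontalpole	L	30	left frontalpole
lh_temporalpole	L	31	left temporalpole
lh_transversetemporal	L	32	left transversetemporal
lh_insula	L	33	left insula
rh_bankssts	R	34	right bankssts
rh_caudalanteriorcingulate	R	35	right caudalanteriorcingulate
rh_caudalmiddlefrontal	R	36	right caudalmiddlefrontal
rh_cuneus	R	37	right cuneus
rh_entorhinal	R	38	right entorhinal
rh_fusiform	R	39	right fusiform
rh_inferiorparietal	R	40	right inferiorparietal
rh_inferiortemporal	R	41	right inferiortemporal
rh_isthmuscingulate	R	42	right isthmuscingulate
rh_lateraloccipital	R	43	right lateraloccipital
rh_lateralorbitofrontal	R	44	right lateralorbitofrontal
rh_lingual	R	45	right lingual
rh_medialorbitofrontal	R	46	right medialorbitofrontal
rh_middletemporal	R	47	right middletemporal
rh_parahippocampal	R	48	right parahippocampal
rh_paracentral	R	49	right paracentral
rh_parsopercularis	R	50	right parsopercularis
rh_parsorbitalis	R	51	right parsorbitalis
rh_parstriangularis	R	52	right parstriangularis
rh_pericalcarine	R	53	right pericalcarine
rh_postcentral	R	54	right postcentral
rh_posteriorcingulate	R	55	right posteriorcingulate
rh_precentral	R	56	right precentral
rh_precuneus	R	57	right precuneus
rh_rostralanteriorcingulate	R	58	right rostralanteriorcingulate
rh_rostralmiddlefrontal	R	59	right rostralmiddlefrontal
rh_superiorfrontal	R	60	right superiorfrontal
rh_superiorparietal	R	61	right superiorparietal
rh_superiortemporal	R	62	right superiortemporal
rh_supramarginal	R	63	right supramarginal
rh_frontalpole	R	64	right frontalpole
rh_temporalpole	R	65	right temporalpole
rh_transversetemporal	R	66	right transversetemporal
rh_insula	R	67	right insula
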