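label	network	hemisphere	aun
lh_bankssts	DMN	left	TRUE
lh_caudalanteriorcingulate	VAN	left	FALSE
lh_caudalmiddlefrontal	FPN	left	FALSE
lh_cuneus	VSN	left	FALSE
lh_entorhinal	LBN	left	FALSE
lh_fusiform	VSN	left	FALSE
lh_inferiorparietal	DMN	left	FALSE
lh_inferiortemporal	DMN	left	FALSE
lh_isthmuscingulate	DMN	left	FALSE
lh_lateraloccipital	VSN	left	FALSE
lh_lateralorbitofrontal	LBN	left	FALSE
lh_lingual	VSN	left	FALSE
lh_medialorbitofrontal	LBN	left	FALSE
lh_middletemporal	DMN	left	TRUE
lh_parahippocampal	LBN	left	FALSE
lh_paracentral	SMN	left	FALSE
lh_parsopercularis	FPN	left	FALSE
lh_parsorbitalis	FPN	left	FALSE
lh_parstriangularis	FPN	left	FALSE
lh_pericalcarine	VSN	left	FALSE
lh_postcentral	SMN	left	FALSE
lh_posteriorcingulate	DMN	left	FALSE
lh_precentral	SMN	left	FALSE
lh_precuneus	DMN	left	FALSE
lh_rostralanteriorcingulate	DMN	left	FALSE
lh_rostralmiddlefrontal	FPN	left	FALSE
lh_superiorfrontal	DMN	left	FALSE
lh_superiorparietal	DAN	left	TRUE
lh_superiortemporal	VAN	left	TRUE
lh_supramarginal	VAN	left	TRUE
lh_frontalpole	DMN	left	FALSE
lh_temporalpole	LBN	left	TRUE
lh_transversetemporal	SMN	left	TRUE
lh_insula	VAN	left	TRUE
rh_bankssts	DMN	right	TRUE
rh_caudalanteriorcingulate	VAN	right	FALSE
rh_caudalmiddlefrontal	FPN	right	FALSE
rh_cuneus	VSN	right	FALSE
rh_entorhinal	LBN	right	FALSE
rh_fusiform	VSN	right	FALSE
rh_inferiorparietal	DMN	right	FALSE
rh_inferiortemporal	DMN	right	FALSE
rh_isthmuscingulate	DMN	right	FALSE
rh_lateraloccipital	VSN	right	FALSE
rh_lateralorbitofrontal	LBN	right	FALSE
rh_lingual	VSN	right	FALSE
rh_medialorbitofrontal	LBN	right	FALSE
rh_middletemporal	DMN	right	TRUE
rh_parahippocampal	LBN	right	FALSE
rh_paracentral	SMN	right	FALSE
rh_parsopercularis	FPN	right	FALSE
rh_parsorbitalis	FPN	right	FALSE
rh_parstriangularis	FPN	right	FALSE
rh_pericalcarine	VSN	right	FALSE
rh_postcentral	SMN	right	FALSE
rh_posteriorcingulate	DMN	right	FALSE
rh_precentral	SMN	right	FALSE
rh_precuneus	DMN	right	FALSE
rh_rostralanteriorcingulate	DMN	right	FALSE
rh_rostralmiddlefrontal	FPN	right	FALSE
rh_superiorfrontal	DMN	right	FALSE
rh_superiorparietal	DAN	right	TRUE
rh_superiortemporal	VAN	right	TRUE
rh_supramarginal	VAN	right	TRUE
rh_frontalpole	DMN	right	FALSE
rh_temporalpole	LBN	right	TRUE
rh_transversetemporal	SMN	right	TRUE
rh_insula	VAN	right	TRUE
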