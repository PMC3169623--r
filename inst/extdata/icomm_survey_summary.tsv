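realm	ecosystem	n_samples	n_sequences	n_otus	n_singletons
pelagic	coastal	194	2561067	20364	10770
pelagic	surface_open_ocean	70	1570433	8995	4223
pelagic	deep_open_ocean	61	1161147	10846	4940
pelagic	vent	14	911066	15072	7290
pelagic	anoxic	17	262995	3759	1477
pelagic	total	356	6466708	44493	23103
benthic	coastal	72	1624189	59051	27648
benthic	deep_seafloor	68	1323228	40680	18544
benthic	vent	13	173725	2885	1169
benthic	total	153	3121142	89168	41831
all	grand_total	509	9587850	120436	59913
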