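rsid	gene	beta	ci_low	ci_high	weight
rs12785878	DHCR7	0.001	-0.010	0.009	1
rs10741657	CYP2R1	-0.005	-0.004	0.010	1
rs2282679	GC	0.001	-0.011	0.010	1
rs6013897	CYP24A1	0.003	-0.008	0.014	1
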