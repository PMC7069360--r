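name	scaffold_id	start	end	strand	q_start	q_end	divergence	indel_rate	placement_class	planted_len	expected_detectable
plant004	scaffold_edge004	0	346	-	1151	1497	0.03	0.002	edge_start	346	FALSE
plant005	scaffold_mito005	5	553	-	899	1447	0.03	0.002	contamination	548	FALSE
plant001	scaffold001	6673	7030	-	854	1211	0.06	0.003	interior	357	TRUE
plant002	scaffold002	1953	2361	-	556	964	0.06	0.003	interior	408	TRUE
plant003	scaffold003	5325	5887	-	300	863	0.06	0.003	interior	562	TRUE
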