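reaction_id	parameter	value	units	provenance
r_aa_release_er	kcat	200	1/h	placeholder
r_aa_release_er	Km	20	uM	placeholder
r_aa_release_golgi	kcat	200	1/h	placeholder
r_aa_release_golgi	Km	20	uM	placeholder
r_aa_reacylation	k	2	1/h	placeholder
r_cox1	kcat	800	1/h	placeholder
r_cox1	Km	5	uM	placeholder
r_cox2	kcat	3000	1/h	placeholder
r_cox2	Km	5	uM	placeholder
r_pgd_synthase	kcat	2000	1/h	placeholder
r_pgd_synthase	Km	3	uM	placeholder
r_pge_synthase	kcat	1500	1/h	placeholder
r_pge_synthase	Km	5	uM	placeholder
r_pgf_synthase	kcat	500	1/h	placeholder
r_pgf_synthase	Km	10	uM	placeholder
r_pgi_synthase	kcat	1000	1/h	placeholder
r_pgi_synthase	Km	10	uM	placeholder
r_tx_synthase	kcat	2500	1/h	placeholder
r_tx_synthase	Km	4	uM	placeholder
r_txa2_hydrolysis	k	80	1/h	placeholder
r_alox5_hpete	kcat	600	1/h	placeholder
r_alox5_hpete	Km	10	uM	placeholder
r_alox5_lta4	kcat	600	1/h	placeholder
r_alox5_lta4	Km	8	uM	placeholder
r_lta4_hydrolase	kcat	800	1/h	placeholder
r_lta4_hydrolase	Km	6	uM	placeholder
r_ltc4_synthase	kcat	400	1/h	placeholder
r_ltc4_synthase	Km	6	uM	placeholder
r_alox12	kcat	300	1/h	placeholder
r_alox12	Km	15	uM	placeholder
r_alox15	kcat	300	1/h	placeholder
r_alox15	Km	15	uM	placeholder
r_secr_pgd2	k	5	1/h	placeholder
r_secr_pge2	k	5	1/h	placeholder
r_secr_txb2	k	5	1/h	placeholder
r_secr_ltb4	k	5	1/h	placeholder
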