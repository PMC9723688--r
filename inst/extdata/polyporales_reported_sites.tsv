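# Published per-sample verification counts for five Polyporales species
# (19 mycelium samples; substrate-days sample naming). Columns: previously
# reported candidate RNA-editing sites, sites removed because the gDNA read
# alignments show the identical variant, sites absent under the newer RNA
# re-alignment, sites matched in raw pooled gDNA reads (a lo-hi range where
# published as such), and sites attributed to different RNA/DNA source
# isolates (NA where not itemised).
species	sample_id	n_reported	n_dna_match	n_absent_realignment	n_pooled_match	n_retained
Daedalea quercina L-15889	Dquercina_Aspen-5D	435	421	13	0	1
Daedalea quercina L-15889	Dquercina_Pine-5D	355	347	8	0	0
Daedalea quercina L-15889	Dquercina_Spruce-5D	365	356	8	0	1
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Aspen-5D	1568	1510	45	13	0
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Pine-5D	1761	1690	53	18	0
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Pine-10D	753	716	27	9	1
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Pine-30D	1067	1022	34	11	0
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Spruce-5D	1288	1244	32	12	0
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Spruce-10D	901	863	33	5	0
Fomitopsis pinicola FP-58527 SS1	Fpinicola_Spruce-30D	1098	1051	38	9	0
Laetiporus sulphureus 93-53	Lsulphureus_Aspen-5D	1328	1297	26	5	0
Laetiporus sulphureus 93-53	Lsulphureus_Pine-5D	1339	1314	21	4	0
Laetiporus sulphureus 93-53	Lsulphureus_Spruce-5D	1304	1282	19	3	0
Wolfiporia cocos MD-104 SS10	Wcocos_Aspen-5D	184	148	35	0	1
Wolfiporia cocos MD-104 SS10	Wcocos_Pine-5D	212	173	38	1	0
Wolfiporia cocos MD-104 SS10	Wcocos_Spruce-5D	195	153	42	0	0
Antrodia sinuosa	Asinuosa_Aspen-5D	1141	698	NA	139-304	NA
Antrodia sinuosa	Asinuosa_Pine-5D	1504	923	NA	229-352	NA
Antrodia sinuosa	Asinuosa_Spruce-5D	936	568	NA	110-258	NA
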