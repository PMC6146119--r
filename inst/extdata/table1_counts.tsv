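class	original_count	filtered_count	ad_count
Cancer	627	159	65
Cardiovascular	395	110	20
Connective tissue	52	30	4
Dermatological	338	129	13
Developmental	409	161	7
Digestive system	128	40	14
Ear, nose, throat	81	22	2
Endocrine	259	85	11
Hematological	333	162	16
Immunological	251	122	29
Metabolic	503	357	40
Multiple	741	374	28
Muscular	263	74	21
Neurological	603	241	46
Nutritional	39	8	2
Ophthalmological	459	141	15
Psychiatric	126	33	4
Renal	99	50	7
Respiratory	52	21	9
Skeletal	313	153	16
Unclassified	134	80	7
Urogenital disease	10	5	2
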