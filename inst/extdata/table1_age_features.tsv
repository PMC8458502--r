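feature_id	mz	rt	signed_p	putative_name	formula	msi_level_printed	inhouse_spectral	public_spectral	in_silico_structure	class_only	formula_only
pos1168	98.05	37.58	0.040	Cyano-hydroxy-butene		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos207	120.04	265.57	0.026	S-Acetylthioethanolamine		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos245	143.11	43.03	0.024			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos175	157.04	39.88	0.018	Hydroxyoxoheptdienoate		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos726	158.08	145.80	0.019	N-Acetylproline		1	TRUE	FALSE	FALSE	FALSE	FALSE
pos171	158.08	58.84	0.022	Paramethadione		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos441	166.07	51.89	0.010	N-Methylguanine		1	FALSE	TRUE	FALSE	FALSE	FALSE
pos1046	180.08	257.27	0.021	7-Aminomethyl-7-carbaguanine		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos266	195.07	72.04	0.014	N-Dimethyluric acid		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos170	195.11	319.97	0.026	N-Hydroxypseudooxynicotine		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos537	196.06	317.68	0.020	Dopaquinone		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos121	197.08	451.26	0.024			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos1075	197.13	421.64	0.030	Alpha amino acid		4	FALSE	FALSE	FALSE	TRUE	FALSE
pos1147	197.13	413.42	0.029	C10H16N2O2	C10H16N2O2	-	FALSE	FALSE	FALSE	FALSE	TRUE
pos477	203.08	63.90	0.023	alpha,beta-Didehydrotryptophan		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos102	209.13	340.59	0.037	Pilocarpine		3	FALSE	TRUE	FALSE	FALSE	FALSE
pos324	212.10	71.87	0.017	N,N-Dideoxycytidine		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos1061	213.16	419.33	0.027	Bipiperidine carboxylic acid		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos568	221.09	63.86	0.022	5-Hydroxy-L-tryptophan	C11H12N2O3	1	TRUE	FALSE	FALSE	FALSE	FALSE
pos296	226.08	44.75	0.018	Acycloguanosine/hypoxanthine		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos180	227.14	340.68	0.036	Barbiturate/pyrimidone		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos99	227.17	488.20	0.037	Diazacyclotetradecanedione		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos75	238.11	417.12	0.021	Cyclocytidine/alkyl aryl ether		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos697	258.66	339.78	0.012			-	FALSE	FALSE	FALSE	TRUE	FALSE
pos588	266.14	338.12	0.042	N-Benzyloxycarbonyl-L-leucine		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos285	277.12	425.06	0.024	Pentalenolactone		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos1054	580.06	408.41	0.013	Mannopinic acid		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos328	312.15	330.58	0.016	Morphinan		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos865	316.16	461.10	0.026	Nitroestrone		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos361	326.04	340.04	0.021	Urothion		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos513	330.17	330.70	0.016			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos927	393.16	346.68	0.021	Ethyl-hydroxy-camptothecin		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos928	415.22	361.01	0.015	Deacetylvindoline		3	FALSE	FALSE	TRUE	FALSE	FALSE
pos887	422.21	310.11	0.039	Fenpyroximate		2	FALSE	TRUE	FALSE	FALSE	FALSE
pos719	425.20	354.18	0.019			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos820	456.19	421.86	0.019			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos1148	469.16	653.96	0.018			-	FALSE	FALSE	FALSE	FALSE	FALSE
pos1035	742.33	401.81	0.018	Benzenesulfonamide analog		4	FALSE	FALSE	FALSE	TRUE	FALSE
pos1064	745.35	409.10	0.038	Cyclic peptide		4	FALSE	FALSE	FALSE	TRUE	FALSE
pos1033	745.51	409.00	0.037	Asparagine and derivatives		4	FALSE	FALSE	FALSE	TRUE	FALSE
pos1037	790.15	414.75	0.049	Benzenesulfonamide analog		4	FALSE	FALSE	FALSE	TRUE	FALSE
pos1109	807.77	400.24	0.056			-	FALSE	FALSE	FALSE	FALSE	TRUE
neg5	125.87	47.04	-0.005			-	FALSE	FALSE	FALSE	FALSE	FALSE
neg446	132.88	32.29	-0.002			-	FALSE	FALSE	FALSE	FALSE	FALSE
neg553	133.04	49.06	0.038	2-Deoxy-D-ribose		1	FALSE	TRUE	FALSE	FALSE	FALSE
neg436	147.04	351.62	0.023	N-Nonatriene-N-diol		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg230	165.05	351.48	0.019	N,N-Dihydroxyphenyllactic acid		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg227	184.94	40.23	-0.012	Ethynylphosphinic acid		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg301	187.00	299.82	0.016	P-cresol sulfate		2	TRUE	FALSE	FALSE	FALSE	FALSE
neg273	205.03	54.29	0.014	N-methylcitrate		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg466	215.13	81.75	0.018	Valine and derivatives		4	FALSE	FALSE	FALSE	TRUE	FALSE
neg461	219.07	63.12	0.028	N-Hydroxy-L-tryptophan		1	TRUE	FALSE	FALSE	FALSE	FALSE
neg306	225.08	157.82	0.016	N,N-Dihydroxy-alpha-methylstilbene		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg334	236.09	409.59	0.022	Tetrahydroisoquinoline		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg417	240.05	306.99	0.023	N,N-Dihydroxybenzoylserine		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg214	260.02	50.71	0.014	Phosphotyrosine		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg279	263.10	312.55	0.048	Phenylacetyl-L-glutamine		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg474	264.98	351.54	0.022	Naphthalene sulfonic acid		3	FALSE	FALSE	TRUE	FALSE	FALSE
neg523	275.10	417.93	0.032	Pyroglutamyl-phenylalanine		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg304	283.06	92.23	0.027	Xanthosine		2	FALSE	TRUE	FALSE	FALSE	FALSE
neg540	302.05	58.02	0.015	Benzo-1,2,3-triazine		3	FALSE	FALSE	TRUE	FALSE	FALSE
neg407	310.11	247.37	0.017	Kainoid		3	FALSE	FALSE	TRUE	FALSE	FALSE
neg207	310.96	47.31	0.014	Benzeneacetic acid analog		4	FALSE	FALSE	FALSE	TRUE	FALSE
neg336	315.95	92.45	0.011	C12H9Cl2NO3S	C12H9Cl2NO3S	-	FALSE	FALSE	FALSE	FALSE	TRUE
neg291	328.15	318.92	0.015	Terpene glycoside		4	FALSE	FALSE	TRUE	FALSE	FALSE
neg176	332.95	46.51	0.011	Hydantoin		3	FALSE	FALSE	TRUE	FALSE	FALSE
neg311	378.81	40.84	-0.005			-	FALSE	FALSE	FALSE	FALSE	FALSE
neg386	389.09	444.39	0.028	Iridoid O-glycoside		3	FALSE	FALSE	TRUE	FALSE	FALSE
neg441	498.72	40.79	-0.005			-	FALSE	FALSE	FALSE	FALSE	FALSE
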