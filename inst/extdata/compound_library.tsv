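compound_id	name	formula
cpd001	5-Hydroxy-L-tryptophan	C11H12N2O3
cpd002	N-Acetylproline	C7H11NO3
cpd003	Paramethadione	C7H11NO3
cpd004	N-Methylguanine	C6H7N5O
cpd005	Dopaquinone	C9H9NO4
cpd006	Pilocarpine	C11H16N2O2
cpd007	p-Cresol sulfate	C7H8O4S
cpd008	Xanthosine	C10H12N4O6
cpd009	Phenylacetyl-L-glutamine	C13H16N2O4
cpd010	2-Deoxy-D-ribose	C5H10O4
cpd011	N-Benzyloxycarbonyl-L-leucine	C14H19NO4
cpd012	Phosphotyrosine	C9H12NO6P
cpd013	2-Methylcitrate	C7H10O7
cpd014	Fenpyroximate	C24H27N3O4
cpd015	Deacetylvindoline	C23H30N2O5
cpd016	Dihydrouracil	C4H6N2O2
cpd017	Kynurenine	C10H12N2O3
cpd018	Tryptophan	C11H12N2O2
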