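level	phylum	taxon	total	IA	IB	IC	IE	I_THERMUS	II	h2_oxidation	sulfur_oxidation	microaerophilic	aerobic	sulfur_reduction	nitrate_reduction	photosynthesis
grand_total		total counts of strains	144	14	1	58	54	7	10	63	46	123	131	32	77	12
phylum		Actinomycetota	58	1		1	53		3	33	3	51	49	2	34	
order	Actinomycetota	Acidimicrobiales	1			1							1	1		
order	Actinomycetota	Actinomycetales	1						1			1	1	1	1	
order	Actinomycetota	Micromonosporales	1	1								1			1	
order	Actinomycetota	Mycobacteriales	7				7			7	1	7			4	
order	Actinomycetota	Propionibacteriales	7				5		2			7	6		1	
order	Actinomycetota	Pseudonocardiales	7				7			3		7	7		4	
order	Actinomycetota	Solirubrobacterales	2				2			2		2	2		1	
order	Actinomycetota	Streptosporangiales	32				32			21	2	26	32		22	
phylum		Bacillota	1				1				1	1		1		
order	Bacillota	Alicyclobacillales	1				1				1	1		1		
phylum		Deinococcota	7					7		1	4		7	7	4	
order	Deinococcota	Thermales	7					7		1	4		7	7	4	
phylum		Pseudomonadota	78	13	1	57			7	29	38	71	75	22	39	12
order	Pseudomonadota	Acetobacterales	3			3					1	3	3		1	1
order	Pseudomonadota	Burkholderiales	20			18			2	4	6	17	18	1	8	1
order	Pseudomonadota	Hyphomicrobiales	13			13				2	3	13	13	1	3	5
order	Pseudomonadota	Lysobacterales	2			2				1	1	2	2			
order	Pseudomonadota	Methylococcales	1	1							1	1	1			
order	Pseudomonadota	Nevskiales	1			1				1		1	1	1		
order	Pseudomonadota	Nitrosomonadales	2			2				2	1	2	2	2	2	
order	Pseudomonadota	Rhodobacterales	16	5		9			3	8	15	14	15	15	11	2
order	Pseudomonadota	Rhodocyclales	3	1		2				2	2	3	3		3	
order	Pseudomonadota	Rhodospirillales	6	2		3			1	5	6	6	6		5	2
order	Pseudomonadota	Sphingomonadales	1			1						1	1			1
order	Pseudomonadota	Steroidobacterales	3			3				1		1	3		2	
order	Pseudomonadota	Thiotrichales	2	1					1	2	2	2	2	2		
order	Pseudomonadota	Vibrionales	5	3	1					1		5	5		4	
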