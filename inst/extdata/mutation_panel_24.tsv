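disease_name	omim_id	gene_symbol	refseq_gene	mrna_id	hgvs_c	hgvs_p	rsid	chrom	pos	ref	alt	inheritance
Sickle cell anemia (SCA)	#603903	HBB	NG_000007.3	NM_000518.4	c.20A>T	p.Glu7Val	rs77121243					autosomal recessive
Primary immunodeficiency (Mucocutaneous fungal infection)	#613108	CLEC7A	NG_016291.1	NM_197947.2	c.714T>G	p.Tyr238*	rs16910526					autosomal recessive
Pituitary hormone deficiency, combined 2 (CPHD2)	#262600	PROP1	NG_015889.1	NM_006261.4	c.301_302delAG	p.Leu102Cysfs*8	rs193922688					autosomal recessive
Canavan disease	#271900	ASPA	NG_008399.1	NM_000049.2	c.854A>C	p.Glu285Ala	rs28940279					autosomal recessive
Canavan disease	#271900	ASPA	NG_008399.1	NM_000049.2	c.914C>A	p.Ala305Glu	rs28940574					autosomal recessive
Pustular psoriasis	No description	AP1S3	NG_034017.1	NM_001039569.1	c.11T>G	p.Phe4Cys	rs116107386					autosomal recessive
Pustular psoriasis	No description	AP1S3	NG_034017.1	NM_001039569.1	c.64A>G	p.Thr22Ala	rs149183052					autosomal recessive
Pustular psoriasis	No description	AP1S3	NG_034017.1	NM_001039569.1	c.95C>T	p.Thr32Ile	rs78536455					autosomal recessive
Pustular psoriasis	No description	AP1S3	NG_034017.1	NM_001039569.1	c.97C>T	p.Arg33Trp	rs138292988					autosomal recessive
Rod-cone dystrophy (RCD)	#615780	PLK1S1	NG_033122.1	NM_018474.4	c.226C>T	p.Arg76*	rs202210819					autosomal recessive
Primary autosomal recessive microcephaly 1 (MCPH1)	#251200	MCPH1	NG_016619.1	NM_024596.3	c.74C>G	p.Ser25*	rs121434305					autosomal recessive
Seckel syndrome 5 (SCKL5)	#613823	CEP152	NG_027518.1	NM_001194998.1	c.2000A>G	p.Lys667Arg	rs200879436					autosomal recessive
Seckel syndrome 5 (SCKL5)	#613823	CEP152	NG_027518.1	NM_001194998.1	c.2034T>G	p.Tyr678*	rs182018947					autosomal recessive
Pontocerebellar hypoplasia type 1B (PCH1B)	#614678	EXOSC3	NG_032780.1	NM_001002269.1	c.238G>T	p.Val80Phe	rs374550999					autosomal recessive
Pontocerebellar hypoplasia type 1B (PCH1B)	#614678	EXOSC3	NG_032780.1	NM_001002269.1	c.395A>C	p.Asp132Ala	rs141138948					autosomal recessive
Miller syndrome	#263750	DHODH	NG_016271.1	NM_001361.4	c.475-1269A>G		rs370087266					autosomal recessive
Miller syndrome	#263750	DHODH	NG_016271.1	NM_001361.4	c.403C>T	p.Arg135Cys	rs201230446					autosomal recessive
Miller syndrome	#263750	DHODH	NG_016271.1	NM_001361.4	c.454G>A	p.Gly152Arg	rs267606766					autosomal recessive
Miller syndrome	#263750	DHODH	NG_016271.1	NM_001361.4	c.1036C>T	p.Arg346Trp	rs201947120					autosomal recessive
Facial dysmorphism, lens dislocation, anterior-segment abnormalities, and spontaneous filtering blebs (FDLAB, Traboulsi syndrome)	#601552	ASPH	NG_013210.1	NM_004318.3	c.2203C>T	p.Arg735Trp	rs374385878					autosomal recessive
Carpenter syndrome 1 (CRPT1)	#201000	RAB23	NG_012170.1	NM_016277.4	c.434T>A	p.Leu145*	rs121908171					autosomal recessive
Glucocorticoid deficiency 4 (GCCD4)	#614736	NNT	NG_032869.1	NM_012343.3	c.1990G>A	p.Gly664Arg	rs371979800					autosomal recessive
Aicardi-Goutieres syndrome 6 (AGS6)	#615010	ADAR	NG_011844.1	NM_001111.4	c.577C>A	p.Pro193Ala	rs145588689					autosomal recessive
MEGDEL syndrome	#614739	SERAC1	NG_032889.1	NM_032861.3	c.1627_1628insTC	p.Ser543Phefs*44	-	6	158571000	A	ATC	autosomal recessive
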