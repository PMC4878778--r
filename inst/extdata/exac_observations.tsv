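mutation_key	disease_name	population	cohort	ac	an
HBB:c.20A>T	Sickle cell anemia (SCA)	African	ExAC	505	10404
HBB:c.20A>T	Sickle cell anemia (SCA)	Latino	ExAC	12	11548
HBB:c.20A>T	Sickle cell anemia (SCA)	South Asian	ExAC	9	16512
HBB:c.20A>T	Sickle cell anemia (SCA)	European (Non-Finnish)	ExAC	6	66734
HBB:c.20A>T	Sickle cell anemia (SCA)	East Asian	ExAC	0	8620
HBB:c.20A>T	Sickle cell anemia (SCA)	European (Finnish)	ExAC	0	6614
HBB:c.20A>T	Sickle cell anemia (SCA)	Other	ExAC	0	908
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	African	ExAC	253	10404
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	Latino	ExAC	395	11578
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	South Asian	ExAC	1593	16510
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	European (Non-Finnish)	ExAC	6	66734
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	East Asian	ExAC	0	8620
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	European (Finnish)	ExAC	0	6614
CLEC7A:c.714T>G	Primary immunodeficiency (Mucocutaneous fungal infection)	Other	ExAC	0	908
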