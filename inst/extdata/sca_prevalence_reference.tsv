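population	expected_af_low	expected_af_high	source
AA	0.0447	0.0577	CDC
AFR	0.0447	0.0577	CDC
AMR	0.00527	0.0316	CDC;Morton2013
ASN	0	0	Modell2008;Piel2013
ASW	0.0447	0.0577	CDC
CHB	0	0	Piel2013
CHS	0	0	Piel2013
CLM	0.008	0.008	Piel2013
FIN	0	0	Piel2013
GBR	0.009	0.009	Piel2013
IBS	0.007	0.007	Piel2013
JPT	0	0	Piel2013
LWK	0.038	0.038	Piel2013
MXL	0.007	0.007	Piel2013
PUR	0.004	0.004	Piel2013
TSI	0.005	0.005	Piel2013
YRI	0.171	0.171	Piel2013
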