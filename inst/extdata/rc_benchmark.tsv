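complex	pdb_id	copy	category	d_his_asp	d_rxn	r_mg	group_published	direction	mg_modeled_from	note
Spo0F:Spo0B	2FTK	1	phosphorelay	5.7	4.1	0.82	I	PAsp_to_His
Spo0F:Spo0B	2FTK	2	phosphorelay	5.3	3.8	0.74	I	PAsp_to_His
Spo0F:Spo0B	2FTK	3	phosphorelay	5.1	3.6	0.65	I	PAsp_to_His
Spo0F:Spo0B	2FTK	4	phosphorelay	5.1	3.5	0.67	I	PAsp_to_His
SLN1:YPD1	2R25	1	phosphorelay	4.9	3.2	0.67	I	PAsp_to_His
AHK5:AHP1	4EUK	1	phosphorelay	6.4	NA	0.72	I	PAsp_to_His		no phosphoryl surrogate present
ChpT:CtrA	4QPJ	1	phosphorelay	5.9	NA	0.64	I	PHis_to_Asp	3GL9	cation transplanted by receiver superposition; one productive ASU copy
CpxA:ATP	4BIW	1	autophosphorylation	5.0	3.4	0.82	I	ATP_to_His		distance to beta-gamma bridging position
HK853-EnvZ:ATP	4KP4	1	autophosphorylation	5.3	3.6	0.72	I	ATP_to_His		distance to beta-gamma bridging position
imidazole:CheY	5DKF	1	imidazole_phosphorylation	5.1	3.3	0.71	I	PAsp_to_imidazole
imidazole:CheY	5DKF	2	imidazole_phosphorylation	5.1	3.3	0.73	I	PAsp_to_imidazole
HK853:RR468	3DGE	1	hk_rr	7.6	5.7	0.51	II	PHis_to_Asp	3GL9	Asp and phosphorus positions refined by receiver superposition
HK853:RR468	3DGE	2	hk_rr	8.0	6.1	0.48	II	PHis_to_Asp	3GL9	Asp and phosphorus positions refined by receiver superposition
DesK:DesR	5IUK	1	hk_rr	7.6	5.8	0.47	II	PHis_to_Asp		phospho-His transplanted from 5IUM
CheA3:CheY6	3KYJ	1	hk_rr	7.3	NA	0.52	II	PHis_to_Asp	4TMY	cation transplanted from template
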