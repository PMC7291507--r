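accession	ortholog	protein_name	reg_low	reg_high
SPLC1_S204380	NIES39_A07260	16S rRNA (uracil(1498)-N(3))-methyltransferase	up	up
SPLC1_S101160	NIES39_Q01000	adenylate cyclase	down	down
SPLC1_S208580	NIES39_K04210	adenylate/guanylate cyclase domain-containing protein	down	up
SPLC1_S082160	NIES39_E03060	aspartyl/glutamyl-tRNA amidotransferase subunit 	up	up
SPLC1_S102760	NIES39_Q02320	beta-ketoacyl-[acyl-carrier-protein] synthase 	up	down
SPLC1_S208940	NIES39_K04600	cell division protein 	up	down
SPLC1_S034010	NIES39_D02960	crossover junction endodeoxyribonuclease Ruv	down	down
SPLC1_S205200	NIES39_A07940	cytochrome c biogenesis protein	up	down
SPLC1_S540320	NIES39_M01840	diguanylate cyclase	down	down
SPLC1_S270810	NIES39_J05180	DNA-binding protein	up	up
SPLC1_S430280	NIES39_O01770	D-tyrosyl-tRNA(Tyr) deacylase	down	up
SPLC1_S270380	NIES39_J05540	glutamate synthase	up	down
SPLC1_S082010	NIES39_E02970	histidine kinase	down	down
SPLC1_S230960	NIES39_L00910	histidine kinase	down	up
SPLC1_S040030	NIES39_D03400	hydrogenase accessory protein Hyp	down	up
SPLC1_S260960	ARTHRO_390015	hydroxymethylbilane synthase	down	down
SPLC1_S051730	NIES39_D06980	hypothetical protein	up	down
SPLC1_S130380	NIES39_R00890	hypothetical protein	down	down
SPLC1_S171520	NIES39_A02180	hypothetical protein	down	up
SPLC1_S202870	NIES39_A05660	hypothetical protein	up	down
SPLC1_S120070	SPLC1_S530570	hypothetical protein	up	down
SPLC1_S510820	NIES39_O06510	IMP dehydrogenase	up	down
SPLC1_S205080	NIES39_A07830	isoaspartyl peptidase	up	up
SPLC1_S060060	NIES39_D06730	lysophospholipase	up	down
SPLC1_S207550	NIES39_K03280	membrane protein	up	down
SPLC1_S410530	NA	MULTISPECIES: HNH endonuclease	down	up
SPLC1_S542340	NA	peptidase	down	down
SPLC1_S201490	NIES39_A04370	phosphate permease	down	up
SPLC1_S240360	NIES39_K02580	phosphoglycerate dehydrogenase	up	up
SPLC1_S082540	NIES39_C04520	CpcD phycobilisome linker domain protein	down	down
SPLC1_S203810	NIES39_A06620	type I restriction endonuclease subunit 	down	down
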