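no	peptide	protein
1	GVIEEAISEINLELEER	Excinuclease ABC subunit B
2	QKEIFIEFEEDGEYMYFLFHRDK	Hypothetical protein
3	EIFDGEMGIYAIHAGVECGIIK	Aminoacyl-histidine dipeptidase
4	VYSGVTINNVDVSGLSR	Vancomycin B-type resistance protein VanW
5	NFETGTLGDLIK	DUF4214 domain-containing protein
6	EMMDQPEFK	DUF4214 domain-containing protein
7	LNEEIKEIVAR	Type I restriction-modification system subunit M
8	LVVAVSNAHYIEK	PolC-type DNA polymerase III
9	DYKEIEDVIKEIYK	PolC-type DNA polymerase III
10	VADSMFLNFWWTTNR	Endo-beta-N-acetylglucosaminidase
11	EKTDGVELQVGANK	Flagellar biosynthesis protein FliC
12	DRNLDVTISIVDR	Flagellar biosynthesis protein FliC
13	AILSEGVELIK	Protein kinase
14	KLEKESNYVLK	DNA ligase (NAD(+)) LigA
15	EKIEVMPVEYEK	Carboxyl-terminal processing protease
16	SLVEVPSDNDLEK	ATP-dependent protease, Lon family
17	RSMVEKNGK	Fe-S cluster assembly protein SufB
18	KSGLDQLIVK	GTP-binding protein YchF
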