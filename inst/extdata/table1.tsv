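probe_id	control	wcr_untreated	wcr_treated	annotation
MZ00004486	0.28629	−0.70834	0.42204	Pathogenesis related protein-1
MZ00042168	0.27636	−2.00827	1.73191	Pathogenesis related protein-1
MZ00043035	0.29500	−1.26578	0.97078	Chitinase
MZ00000977	−0.14194	−0.37386	0.51580	Putative antifungal thaumatin-like protein
MZ00013547	−0.03908	−1.00381	1.04289	Thaumatin-like protein
MZ00044339	0.26643	−0.53451	0.26808	Cysteine proteinase inhibitor
MZ00035455	−0.13164	−0.87217	1.00381	Cysteine proteinase CP1
MZ00038348	0.43674	−0.92740	0.49066	Cathepsin B-like cysteine proteinase
MZ00002045	−0.09321	−0.34906	0.44227	Putative aspartic proteinase nepenthesin I
MZ00025326	−0.07839	−0.46348	0.54187	Aspartic proteinase
MZ00018372	−0.09187	−0.50369	0.59556	Class III chitinase RCB4
MZ00037339	0.03418	−0.64691	0.61273	Chitinase
MZ00021144	−0.10106	−0.48489	0.58595	Putative Peroxidase 1 precursor
MZ00022862	−0.20443	0.01207	2.05420	Class III peroxidase
MZ00033093	−0.01601	−1.55862	1.57463	Putative peroxidase P7X
MZ00027915	−0.05187	−1.12610	1.17797	Pathogenesis-related protein 10
MZ00028247	0.49832	−2.62245	2.12414	Putative aleurone ribonuclease
MZ00043949	0.08557	−1.05327	0.96771	Defensin 1 precursor
MZ00016209	0.00094	0.64830	0.00000	Thionin
MZ00003835	0.33676	−1.67161	1.33486	Putative lipid transfer protein
MZ00039775	0.10281	−0.48354	0.38073	Xylanase inhibitor protein I
MZ00036538	−0.41536	−2.10232	2.51768	Subtilisin/chymotrypsin inhibitor
MZ00025431	−0.03244	−0.73077	0.76321	Bowman-Birk type trypsin inhibitor
MZ00011113	0.01716	0.15841	0.69393	OTU-like cysteine protease-like
MZ00005428	−0.81427	0.01629	0.79798	4-hydroxycinnamic acid-CoA ligase
MZ00044023	−0.03263	−0.69551	0.72814	Cinnamoyl-CoA reductase
MZ00014292	1.32518	1.17489	3.59778	Phenylalanine ammonia-lyase
MZ00025513	−0.55650	−0.46633	1.02284	Cinnamic acid 4-hydroxylase
MZ00028764	0.07526	−0.46305	0.38778	Dihydroflavonol4-reductase
MZ00026160	0.79660	−0.60977	1.92247	Glutathione S-transferase GST 30
MZ00041712	−0.38460	−0.43680	0.82140	Glutathione S-transferase GST 8
MZ00015236	3.08190	2.10015	5.06733	UDP-glucosyltransferase BX9
MZ00012679	−0.27730	−0.95516	1.04017	Probable hydroquinone glucosyltransferase
MZ00000005	−0.39050	−0.67223	1.06273	Lipoxygenase
MZ00043996	−0.16248	−0.94616	1.10864	Bax inhibitor-1
MZ00032776	0.02366	−0.30412	0.28045	Putative disease resistance response protein
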