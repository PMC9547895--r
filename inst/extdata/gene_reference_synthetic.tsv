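rank	name	mean_gene_count
genus	Genus001	2213
species	species002	3604
species	species003	2771
species	species004	8000
species	species005	2941
species	species006	5056
species	species007	1765
species	species008	5913
species	species009	1919
species	species010	1932
genus	Genus011	3858
species	species013	2293
species	species014	4734
species	species015	4277
species	species016	3260
species	species017	2439
species	species018	6055
species	species019	2007
species	species020	7901
species	species021	2132
species	species022	7387
species	species023	4350
species	species024	5648
species	species025	1664
species	species026	2932
species	species027	1673
species	species028	4679
species	species029	1500
species	species030	4033
species	species031	2936
genus	Genus032	8000
species	species033	2656
species	species034	3242
species	species035	1619
species	species037	3890
species	species038	5036
genus	Genus039	8000
species	species040	6966
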