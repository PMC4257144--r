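# Published per-target specificities for the hg_structal (A),
# 4state_reduced (B) and fisa (C) decoy sets.
Set	PDB	NRes	NStructures	Specificity
hg_structal	2PGHA	141	30	0.2
hg_structal	1MBS	153	30	0.5
hg_structal	2DHBA	141	30	0.6
hg_structal	1HDAB	145	30	0.9
hg_structal	1MYT	146	30	0.9
hg_structal	1HLM	158	30	0.9
hg_structal	1HSY	153	30	0.9
hg_structal	1MBA	146	30	0.9
hg_structal	1MYGA	153	30	0.9
hg_structal	1MYJA	153	30	0.9
hg_structal	1ASH	147	30	1
hg_structal	1BABB	146	30	1
hg_structal	1COLA	197	30	1
hg_structal	1CPCA	162	30	1
hg_structal	1ECD	136	30	1
hg_structal	1EMY	153	30	1
hg_structal	1FLP	142	30	1
hg_structal	1GDM	153	30	1
hg_structal	1HBG	147	30	1
hg_structal	1HBHA	142	30	1
hg_structal	1HBHB	146	30	1
hg_structal	1HDAA	141	30	1
hg_structal	1HLB	157	30	1
hg_structal	1ITHA	141	30	1
hg_structal	1LHT	153	30	1
hg_structal	2DHBB	146	30	1
hg_structal	2LHB	149	30	1
hg_structal	2PGHB	146	30	1
hg_structal	4SDHA	145	30	1
4state_reduced	2CRO	65	675	0.8
4state_reduced	3ICB	75	654	0.9
4state_reduced	4RXN	54	677	0.9
4state_reduced	4PTI	118	688	1
4state_reduced	1CTF	131	631	1
4state_reduced	1R69	97	676	1
4state_reduced	1SN3	65	661	1
fisa	4ICB	76	501	0
fisa	1FC2	44	501	0.4
fisa	1HDDC	57	501	0.1
fisa	2CRO	65	501	0.7
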