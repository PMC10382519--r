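# Curated biochemical phenotype panel of 15 FBP1 missense mutations.
# expression_ratio is mutant/WT protein expression; aggregation_pct is the
# percentage of cells with FBP1 aggregates; hsp70/hsp90 are chaperone
# binding ratios vs WT. type is the published functional category. v1
mutation	type	location	activity_call	expression_call	expression_ratio	localization	aggregation_pct	hsp70_ratio	hsp90_ratio	wt_class	mut_class	wt_hydropathy	mut_hydropathy	secondary_structure
D119N	1	metal binding site	decrease	no_change	1.4	diffuse	9.4	0.1	0.3	hydrophilic-acidic	hydrophilic-neutral	-3.5	-3.5	beta-strand
P120L	1	linker between metal and substrate binding sites	decrease	no_change	1.3	diffuse	8.5	1.1	0.5	hydrophobic-aliphatic	hydrophobic-aliphatic	-1.6	3.8	beta-strand
N213K	1	substrate binding site	decrease	no_change	1.1	diffuse	13.3	1.5	0.5	hydrophilic-neutral	hydrophilic-basic	-3.5	-3.9	ND
E281K	1	metal binding site	decrease	no_change	0.9	diffuse	33.6	2.4	0.5	hydrophilic-acidic	hydrophilic-basic	-3.5	-3.9	turn
R158W	2		decrease	decrease	0.5	aggregated_ER	69.6	7.7	7.8	hydrophilic-basic	hydrophobic-aromatic	-4.5	-0.9	alpha-helix
G164D	2		decrease	decrease	0.4	aggregated_ER	71.4	13.7	15.8	hydrophobic-aliphatic	hydrophilic-acidic	-0.4	-3.5	beta-strand
G164S	2		decrease	decrease	0.6	aggregated_ER	42.7	6.4	12.2	hydrophobic-aliphatic	hydrophilic-neutral	-0.4	-0.8	beta-strand
A177D	2		decrease	decrease	0.2	aggregated_ER	73.9	24.0	37.5	hydrophobic-aliphatic	hydrophilic-acidic	1.8	-3.5	beta-strand
F194S	2		decrease	decrease	0.4	aggregated_ER	62.6	15.4	19.8	hydrophobic-aromatic	hydrophilic-neutral	2.8	-0.8	beta-strand
G260R	2		decrease	decrease	0.4	aggregated_ER	73.5	18.9	28.2	hydrophobic-aliphatic	hydrophilic-basic	-0.4	-4.5	ND
P284R	2		decrease	decrease	0.3	aggregated_ER	57.7	41.2	47.2	hydrophobic-aliphatic	hydrophilic-basic	-1.6	-4.5	alpha-helix
G294E	2		decrease	decrease	0.4	aggregated_ER	64.1	64.9	89.9	hydrophobic-aliphatic	hydrophilic-acidic	-0.4	-3.5	ND
G294V	2		decrease	decrease	0.6	aggregated_ER	65.9	6.1	3.5	hydrophobic-aliphatic	hydrophobic-aliphatic	-0.4	4.2	ND
G207R	3		no_change	no_change	1.0	diffuse	12.7	3.1	3.9	hydrophobic-aliphatic	hydrophilic-basic	-0.4	-4.5	ND
V325A	3		no_change	no_change	1.0	diffuse	25.4	2.3	1.3	hydrophobic-aliphatic	hydrophobic-aliphatic	4.2	1.8	alpha-helix
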