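# Synthetic per-position structure context for the 15-mutation FBP1 panel.
# Distances (Angstrom) are a curated stand-in encoding the published
# qualitative geometry of the FBPase dimer -- misfolding-prone (Type 2)
# positions cluster within the substrate-pocket radius (12 A), active-site
# positions sit in their sites (distance 0 by self-inclusion), and the two
# likely non-pathogenic positions are distant -- not measured coordinates.
# Secondary-structure labels are transcribed from the published panel. v1
position	min_dist_substrate	min_dist_metal	min_dist_amp	secondary_structure
119	4.8	0.0	21.5	beta-strand
120	2.1	1.9	20.8	beta-strand
158	10.5	14.2	17.9	alpha-helix
164	7.2	11.8	24.6	beta-strand
177	8.9	13.5	16.2	beta-strand
194	6.4	10.9	26.3	beta-strand
207	18.4	21.7	28.9	ND
213	0.0	9.6	23.4	ND
260	9.8	12.7	19.5	ND
281	8.7	0.0	25.1	turn
284	11.1	7.4	22.8	alpha-helix
294	8.1	13.1	27.2	ND
325	23.7	26.4	31.6	alpha-helix
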