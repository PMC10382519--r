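# Kyte-Doolittle hydropathy scale with five-way amino-acid class labels.
# Classes for residues present in the curated FBP1 panel follow the panel's
# printed labels; the remaining residues follow standard biochemistry
# conventions (see package vignette). v1
aa	hydropathy	class
A	1.8	hydrophobic-aliphatic
R	-4.5	hydrophilic-basic
N	-3.5	hydrophilic-neutral
D	-3.5	hydrophilic-acidic
C	2.5	hydrophobic-aliphatic
Q	-3.5	hydrophilic-neutral
E	-3.5	hydrophilic-acidic
G	-0.4	hydrophobic-aliphatic
H	-3.2	hydrophilic-basic
I	4.5	hydrophobic-aliphatic
L	3.8	hydrophobic-aliphatic
K	-3.9	hydrophilic-basic
M	1.9	hydrophobic-aliphatic
F	2.8	hydrophobic-aromatic
P	-1.6	hydrophobic-aliphatic
S	-0.8	hydrophilic-neutral
T	-0.7	hydrophilic-neutral
W	-0.9	hydrophobic-aromatic
Y	-1.3	hydrophobic-aromatic
V	4.2	hydrophobic-aliphatic
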