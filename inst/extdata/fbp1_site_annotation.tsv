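# Functional-site residue annotation for human FBP1 (protein numbering).
# Metal-binding, substrate-binding and linker residues are those named in
# the published panel; the AMP allosteric-site list is a minimal synthetic
# stand-in (complete database curation not reproduced here) and no analysis
# in this package depends on its exact membership. v1
site	position
metal	119
metal	121
metal	281
substrate	122
substrate	213
substrate	214
substrate	215
substrate	216
amp	27
amp	28
amp	29
amp	31
amp	112
amp	140
linker	120
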