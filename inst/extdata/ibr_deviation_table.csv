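group,AChE,MT,SOD,CAT,GSH,GST,MDA,PC,protein_energy,glucose_energy,lipid_energy,Ea,Ec,CEA,IBRv2_published
A2,1.02,0.063,0.876,0.372,0.224,0.137,0.564,0.461,0.100,0.337,0.001,0.103,0.782,0.199,5.24
A3,0.168,0.001,0.804,0.821,0.748,0.719,0.341,0.466,0.262,0.810,0.093,0.076,0.034,0.033,5.38
A4,0.055,0.194,0.912,0.703,0.134,1.27,0.604,0.114,0.212,0.719,0.130,0.228,0.036,0.178,5.49
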