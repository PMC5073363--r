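property,value
fame_content,96.72
density,0.85
viscosity,3.64
oxidation_stability,4.74
monoglycerides,<0.1
diglycerides,<0.05
triglycerides,<0.05
free_glycerol,<0.001
total_glycerol,<0.05
group1_metals,0.45
group2_metals,0.05
phosphorus,24.02
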