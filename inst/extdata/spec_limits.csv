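property,standard,lower,upper,inclusive_lower,inclusive_upper,units,note
fame_content,EN14214,96.50,,TRUE,,% (m/m),
density,EN14214,0.86,0.90,TRUE,TRUE,kg/L,at 15 degC
viscosity,EN14214,3.50,5.00,TRUE,TRUE,mm2/s,at 40 degC
cetane_number,EN14214,51,,TRUE,,,
oxidation_stability,EN14214,6,,FALSE,,h,strict bound (>6)
iodine_value,EN14214,,120,,TRUE,g I/100 g,
linolenic_acid,EN14214,,12.0,,TRUE,% (m/m),
pufa_ge4db,EN14214,,1.00,,TRUE,% (m/m),
monoglycerides,EN14214,,0.80,,TRUE,% (m/m),
diglycerides,EN14214,,0.20,,TRUE,% (m/m),
triglycerides,EN14214,,0.20,,TRUE,% (m/m),
free_glycerol,EN14214,,0.02,,TRUE,% (m/m),
total_glycerol,EN14214,,0.25,,TRUE,% (m/m),
group1_metals,EN14214,,5.0,,TRUE,mg/kg,Na + K
group2_metals,EN14214,,5.0,,TRUE,mg/kg,Ca + Mg
phosphorus,EN14214,,4.0,,TRUE,mg/kg,
viscosity,ASTM_D6751,1.90,6.00,TRUE,TRUE,mm2/s,at 40 degC
cetane_number,ASTM_D6751,47,,TRUE,,,
oxidation_stability,ASTM_D6751,3,,FALSE,,h,strict bound (>3)
free_glycerol,ASTM_D6751,,0.02,,TRUE,% (m/m),
total_glycerol,ASTM_D6751,,0.24,,TRUE,% (m/m),
group1_metals,ASTM_D6751,,5.0,,TRUE,mg/kg,Na + K
group2_metals,ASTM_D6751,,5.0,,TRUE,mg/kg,Ca + Mg
phosphorus,ASTM_D6751,,10.0,,TRUE,mg/kg,
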