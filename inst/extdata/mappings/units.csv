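unit,dimension,factor,base_unit
ml/h,volume_rate,1,ml/h
ml/min,volume_rate,60,ml/h
l/h,volume_rate,1000,ml/h
mg/h,mass_rate,1,mg/h
mg/min,mass_rate,60,mg/h
ug/h,mass_rate,0.001,mg/h
ug/min,mass_rate,0.06,mg/h
mcg/h,mass_rate,0.001,mg/h
mcg/min,mass_rate,0.06,mg/h
mg/kg/h,mass_rate_per_kg,1,mg/kg/h
ug/kg/min,mass_rate_per_kg,0.06,mg/kg/h
mg/ml,concentration,1,mg/ml
ug/ml,concentration,0.001,mg/ml
ml,volume_amount,1,ml
l,volume_amount,1000,ml
mg,mass_amount,1,mg
ug,mass_amount,0.001,mg
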