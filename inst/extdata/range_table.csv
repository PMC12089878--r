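variable,phys_low,phys_high,life_low,life_high,outlier_low,outlier_high
fio2,0.21,1,0.21,1,0.1,1
o2_flow,0,15,0,60,0,80
peep,0,20,0,35,0,50
psupp,0,30,0,50,0,60
pinsp,5,35,0,60,0,80
set_rate,6,40,0,60,0,80
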