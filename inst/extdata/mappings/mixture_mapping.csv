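ingredient_set,rel_give_SpO2_low,rel_give_HR_low,rel_give_HR_high,rel_give_IBP_low,rel_give_IBP_high,rel_stop_SpO2_low,rel_stop_HR_low,rel_stop_HR_high,rel_stop_IBP_low,rel_stop_IBP_high
fentanyl+midazolam,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE
glucose_5+potassium_chloride,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
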