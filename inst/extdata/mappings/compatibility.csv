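rst_level,o2_flow_flowmeter,o2_flow_not_flowmeter,fio2,peep,psupp,pinsp,set_rate
1,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
2,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
3,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE
4,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE
5,FALSE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE
6,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,TRUE
7,FALSE,TRUE,TRUE,TRUE,FALSE,TRUE,TRUE
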