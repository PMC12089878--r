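vd_text,vm_text,ad_category,rst_category,rst_level
none,none,,spontaneous_breathing,1
none,spontaneous,,spontaneous_breathing,1
flowmeter,o2 flow,,oxygen_therapy,2
flowmeter,spontaneous,,oxygen_therapy,2
hfnc,high flow,,high_flow_oxygen_therapy,4
ventilator,cpap,,cpap,3
ventilator,cpap,endotracheal_tube,augmented_ventilation,6
ventilator,cpap,tracheal_cannula,augmented_ventilation,6
ventilator,cpap/asb,,noninvasive_ventilation,5
ventilator,cpap/asb,endotracheal_tube,augmented_ventilation,6
ventilator,cpap/asb,tracheal_cannula,augmented_ventilation,6
ventilator,niv,,noninvasive_ventilation,5
ventilator,niv/psv,,noninvasive_ventilation,5
ventilator,bipap,,augmented_ventilation,6
ventilator,bipap/asb,,augmented_ventilation,6
ventilator,simv,,augmented_ventilation,6
ventilator,pcv,,controlled_ventilation,7
ventilator,vcv,,controlled_ventilation,7
ventilator,aprv,,controlled_ventilation,7
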