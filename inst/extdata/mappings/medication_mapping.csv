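drug_id,active_ingredient,snomed_code,route_text,route_category,technique,is_iv_fluid,rel_give_SpO2_low,rel_give_HR_low,rel_give_HR_high,rel_give_IBP_low,rel_give_IBP_high,rel_stop_SpO2_low,rel_stop_HR_low,rel_stop_HR_high,rel_stop_IBP_low,rel_stop_IBP_high
D001,norepinephrine,111130,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE
D002,epinephrine,387362001,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE
D003,dobutamine,387145002,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
D004,nitroglycerin,387404004,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE
D005,clonidine,372806008,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE
D010,propofol,387423006,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE
D011,propofol,387423006,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE,TRUE,FALSE
D012,atropine,372832008,i.v. Bolus,intravenous,bolus,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D013,metoprolol,372826007,i.v. Bolus,intravenous,bolus,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
D014,urapidil,395881001,i.v. Bolus,intravenous,bolus,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE
D015,cafedrine_theodrenaline,703112004,i.v. Bolus,intravenous,bolus,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D016,salbutamol,372897005,inhalativ,inhalation,bolus,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D017,epoprostenol,372513003,inhalativ Vernebler,inhalation,continuous,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D018,iloprost,395740005,inhalativ Vernebler,inhalation,continuous,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D020,sodium_chloride_09,387390002,i.v. Infusion,intravenous,continuous,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D021,balanced_crystalloid,331646006,i.v. Infusion,intravenous,continuous,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D030,midazolam,372890007,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D030,fentanyl,373492002,i.v. Perfusor,intravenous,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D031,glucose_5,346521000,i.v. Infusion,intravenous,continuous,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D031,potassium_chloride,387450001,i.v. Infusion,intravenous,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D040,amlodipine,386864001,per os,oral,bolus,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D041,levothyroxine,710809001,Magensonde,enteral_tube,bolus,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D042,insulin_glargine,411529005,s.c.,subcutaneous,bolus,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D043,haloperidol,386837002,i.m.,intramuscular,bolus,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D044,fentanyl,373492002,transdermal Pflaster,transdermal,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
D045,bupivacaine,387325003,Periduralkatheter,epidural,continuous,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
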