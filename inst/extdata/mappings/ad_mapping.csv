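raw_text,ad_category,ad_level,annotation_flag
no AD documented,no_ad,1,TRUE
kein Atemweg,no_ad,1,TRUE
O2-Brille,nasal_cannula_interface,2,TRUE
Nasenbrille,nasal_cannula_interface,2,TRUE
Maske,face_mask,2,TRUE
Maske,niv_full_face_mask,3,FALSE
O2-Maske,face_mask,2,TRUE
NIV Maske,niv_full_face_mask,3,TRUE
Nasen-NIV,niv_nasal_mask,3,TRUE
Helm,niv_helmet,3,TRUE
Guedel,oropharyngeal_airway,4,TRUE
Wendl,nasopharyngeal_airway,4,TRUE
Larynxmaske,laryngeal_mask,5,TRUE
LMA,laryngeal_mask,5,TRUE
Larynxtubus,laryngeal_tube,5,TRUE
Intubationslarynxmaske,intubating_laryngeal_mask,6,TRUE
Kombitubus,combitube,6,TRUE
Koniotomie,cricothyrotomy_cannula,7,TRUE
Tracheostoma,tracheostomy_tube,8,TRUE
Tracheostoma,tracheal_cannula,9,FALSE
Minitrach,minitracheostomy,8,TRUE
TK ungeblockt,tracheostomy_uncuffed,8,TRUE
Endotracheal tube,endotracheal_tube,9,TRUE
Tubus,endotracheal_tube,9,TRUE
ETT 7.5,endotracheal_tube,9,TRUE
Trachealkanuele,tracheal_cannula,9,TRUE
Befeuchter,non_ad_artifact,0,TRUE
HFNC Geraet,non_ad_artifact,0,TRUE
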