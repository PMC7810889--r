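sample_id,category,project,provenance,ceramic_group,period,form_class,decoration,height_cm,width_cm,aperture_cm,strung,treatment
V01,vessel,PASUC,Ucanha,Muna,L-T,SF_narrow,None,5,5,0.7,yes,untreated
V02,vessel,PASUC,Ucanha,Muna,L-T,EF,Monkey,5.5,5.5,0.8,no,untreated
V03,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Serrated edges,6,7.1,0.8,yes,curated
V04,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Painted; applied buttons,6.9,7.4,0.9,yes,curated
V05,vessel,PARME,N MID,Muna,L-T,PF_narrow,None,6.6,7,0.9,yes,curated
V06,vessel,PARME,N MID,Muna,L-T,PF_narrow,Painted,6.4,7,0.8,yes,curated
V07,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Serrated edges,5.8,6.2,1,yes,curated
V08,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Zoomorphic incision,8.2,9.3,1,yes,curated
V09,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Applied buttons; negative technique painting; incised,5.6,6.4,0.7,no,curated
V10,vessel,PARME,W MID,Muna,L-T,PF_narrow,Painted; applied buttons,7.1,7.8,0.9,yes,curated
V11,vessel,PARME,NE MID,Muna,L-T,PF_narrow,Serrated edges,7.3,8.3,1.2,yes,curated
V12,vessel,PARME,NE MID,Dzitya,L,SF_narrow,Painted; incised,4.8,4.7,1.1,yes,curated
V13,vessel,PARME,NE MID,Aguila,E,SF_wide,Incised,6.4,6.6,2.4,yes,curated
V14,vessel,PARME,W MID,Muna,L-T,SF_wide,Modeled owl face,5.3,5.4,2,yes,curated
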