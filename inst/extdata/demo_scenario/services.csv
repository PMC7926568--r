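"service_id","indicator_id","frequency","setting","service_standard","cadre_id","work_division"
"antenatal_visit","anc_need",8,"primary",0.33,"midwife",0.95
"antenatal_visit","anc_need",8,"tertiary",0.5,"midwife",0.95
"antenatal_visit","anc_need",8,"primary",0.33,"obstetrician_gynaecologist",0.05
"antenatal_visit","anc_need",8,"tertiary",0.5,"obstetrician_gynaecologist",0.05
"normal_delivery","pregnancy_rate",1,"primary",6,"midwife",0.9
"normal_delivery","pregnancy_rate",1,"tertiary",8,"midwife",0.9
"normal_delivery","pregnancy_rate",1,"primary",6,"obstetrician_gynaecologist",0.1
"normal_delivery","pregnancy_rate",1,"tertiary",8,"obstetrician_gynaecologist",0.1
"complicated_delivery","complicated_delivery_rate",1,"primary",8,"midwife",0.25
"complicated_delivery","complicated_delivery_rate",1,"tertiary",10,"midwife",0.25
"complicated_delivery","complicated_delivery_rate",1,"primary",8,"obstetrician_gynaecologist",0.75
"complicated_delivery","complicated_delivery_rate",1,"tertiary",10,"obstetrician_gynaecologist",0.75
"postnatal_visit","pregnancy_rate",4,"primary",0.25,"midwife",1
"postnatal_visit","pregnancy_rate",4,"tertiary",0.33,"midwife",1
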