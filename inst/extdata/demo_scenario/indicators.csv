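"indicator_id","age_cohort","gender","location","baseline_value","baseline_year","second_value","second_year","rate_of_change","rate_method"
"pregnancy_rate","","","",0.142,2007,0.151,2017,"","geometric"
"anc_need","","","",0.135,2007,0.149,2017,"","geometric"
"complicated_delivery_rate","","","",0.021,2007,0.027,2017,"","geometric"
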