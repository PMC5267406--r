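"patient_id","age","sex","admission_source","admission_type","mechanically_ventilated","vasopressor_used","low_risk_monitoring","icu_los_days","outcome"
"P0001",34,"male","obstetric_theatre","medical",TRUE,TRUE,FALSE,4.7,"survived"
"P0002",13,"female","emergency_room","medical",TRUE,TRUE,FALSE,6.4,"survived"
"P0003",21,"male","medical_ward","surgical",TRUE,FALSE,FALSE,6.4,"died"
"P0004",49,"male","emergency_room","medical",TRUE,FALSE,TRUE,11,"survived"
"P0005",21,"male","emergency_room","surgical",FALSE,FALSE,FALSE,3.3,"survived"
"P0006",51,"male","obstetric_theatre","medical",TRUE,FALSE,TRUE,12.7,"died"
"P0007",42,"female","medical_ward","medical",TRUE,TRUE,FALSE,0.8,"survived"
"P0008",32,"female","other_hospital","surgical",TRUE,FALSE,FALSE,1.8,"survived"
"P0009",47,"female","obstetric_gynecology_ward","medical",TRUE,FALSE,FALSE,8.7,"survived"
"P0010",52,"male","medical_ward","medical",TRUE,FALSE,FALSE,12.3,"died"
"P0011",43,"male","emergency_room","medical",TRUE,FALSE,FALSE,7,"survived"
"P0012",13,"female","surgical_ward","surgical",FALSE,TRUE,FALSE,8.9,"died"
"P0013",40,"male","obstetric_gynecology_ward","surgical",FALSE,FALSE,TRUE,17.7,"died"
"P0014",62,"male","medical_ward","medical",TRUE,FALSE,FALSE,1.3,"died"
"P0015",48,"female","emergency_room","surgical",TRUE,FALSE,TRUE,8,"survived"
"P0016",80,"male","medical_ward","surgical",FALSE,FALSE,TRUE,1.6,"survived"
"P0017",48,"male","medical_ward","medical",FALSE,FALSE,TRUE,2.6,"died"
"P0018",18,"male","emergency_room","surgical",FALSE,FALSE,FALSE,4,"died"
"P0019",13,"male","emergency_room","surgical",FALSE,FALSE,FALSE,9,"survived"
"P0020",13,"female","medical_ward","medical",FALSE,FALSE,FALSE,5.1,"died"
"P0021",13,"male","surgical_ward","medical",TRUE,TRUE,FALSE,7.9,"survived"
"P0022",36,"male","emergency_room","medical",TRUE,FALSE,FALSE,4.7,"died"
"P0023",60,"female","other_hospital","medical",TRUE,FALSE,FALSE,2.8,"died"
"P0024",13,"male","operating_room","surgical",FALSE,FALSE,FALSE,2.4,"died"
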