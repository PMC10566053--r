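"id","age","psa_ng_ml","family_history","prior_negative_biopsy","abnormal_dre","risk_group","gleason_sum","cohort"
"S0001",68,4.93,1,0,1,"benign",,"training"
"S0002",76,5.27,0,1,0,"benign",,"training"
"S0003",65,3.34,0,0,0,"VLR",6,"training"
"S0004",69,12.54,0,0,0,"FIR",7,"training"
"S0005",68,12.89,0,0,0,"UIR",7,"training"
"S0006",65,6.92,1,0,0,"HR",10,"training"
"S0007",59,4.78,0,0,1,"VHR",9,"training"
"S0008",58,131.04,0,0,1,"mPC",10,"training"
"S0009",61,9.94,0,0,0,"benign",,"validation"
"S0010",71,5.35,0,0,0,"HR",9,"validation"
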