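patient_id,age,sex,wcc,dauno_dose,regimen,induction_given,cr1_time,cr1_via_salvage,relapse_time,hsct_time,death_time,death_context,last_followup
EX01,34,female,12.5,90,7+3,TRUE,1.2,FALSE,14.5,,20.25,death_in_relapse,20.25
EX02,55,male,3.2,60,7+3,TRUE,1.5,FALSE,,5.5,,none,86
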