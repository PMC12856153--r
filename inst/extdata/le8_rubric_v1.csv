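table,level,lower,upper,points
smoking_status,never,,,100
smoking_status,current,,,0
smoking_former_quit_years,,5,Inf,75
smoking_former_quit_years,,1,5,50
smoking_former_quit_years,,0,1,25
bmi,,-Inf,25,100
bmi,,25,30,70
bmi,,30,35,30
bmi,,35,40,15
bmi,,40,Inf,0
physical_activity_met_min,,600,Inf,100
physical_activity_met_min,,480,600,90
physical_activity_met_min,,360,480,80
physical_activity_met_min,,240,360,60
physical_activity_met_min,,120,240,40
physical_activity_met_min,,4,120,20
physical_activity_met_min,,0,4,0
sleep_hours,,7,9,100
sleep_hours,,9,10,90
sleep_hours,,6,7,70
sleep_hours,,5,6,40
sleep_hours,,10,Inf,40
sleep_hours,,4,5,20
sleep_hours,,0,4,0
bp_sbp,,-Inf,120,100
bp_sbp,,120,130,75
bp_sbp,,130,140,50
bp_sbp,,140,160,25
bp_sbp,,160,Inf,0
bp_dbp,,-Inf,80,100
bp_dbp,,80,90,50
bp_dbp,,90,100,25
bp_dbp,,100,Inf,0
non_hdl_mmol_l,,-Inf,3.36,100
non_hdl_mmol_l,,3.36,4.14,60
non_hdl_mmol_l,,4.14,4.91,40
non_hdl_mmol_l,,4.91,5.69,20
non_hdl_mmol_l,,5.69,Inf,0
hba1c_nondiabetic,,-Inf,39,100
hba1c_nondiabetic,,39,48,60
hba1c_diabetic,,-Inf,53,40
hba1c_diabetic,,53,64,30
hba1c_diabetic,,64,75,20
hba1c_diabetic,,75,86,10
hba1c_diabetic,,86,Inf,0
treatment_deduction,blood_pressure,,,20
treatment_deduction,non_hdl,,,20
diet_quartile_points,q1,,,0
diet_quartile_points,q2,,,33.333333333333336
diet_quartile_points,q3,,,66.66666666666667
diet_quartile_points,q4,,,100
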