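column	type	definition
srh	integer 1..5	self-rated health on a 5-point Likert scale, 5 = very good
income_initial	numeric >= 0	annual per-capita household income, currency units
premium	numeric >= 0	annual insurance premium actually paid (after any subsidy)
oop_spend	numeric >= 0	annual out-of-pocket medical spending, currency units
reimbursement	numeric >= 0	annual insurance reimbursement received; never exceeds oop_spend
outpatient_visits	integer >= 0	annual outpatient visit count
inpatient_episodes	integer >= 0	annual inpatient episode count
gender	binary 0/1	1 = female
age	integer	age in years
education_years	integer >= 0	completed years of schooling
education_group	factor	below_middle_school / middle_school / high_school / above_high_school
marital	binary 0/1	1 = married or cohabiting
urban	binary 0/1	1 = urban resident
region	factor	east / central / west
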