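column	type	range	waves	description
id	integer	>= 1	-	subject identifier, unique within a cohort
wave	integer	1..3	-	survey wave (1 = baseline, 2 = first follow-up, 3 = final follow-up)
female	binary	0/1	all	sex recorded at baseline (1 = female)
ethnicity	category	Chinese/Malay/Indian/Others	all	self-reported ethnic group
low_education	binary	0/1	all	primary school or below (1) vs above primary (0)
housing	category	hdb_1_2/hdb_3/hdb_4_5_private	all	housing type: 1-2 room government-built / 3 room / 4-5 room or private
cognitive_flag	binary	0/1	all	baseline exclusion flag (stand-in for cognitive-impairment screening)
age	numeric	years	1..3	age in years; advances deterministically with the survey calendar
mobility	binary	0/1	1..3	any reported mobility limitation
cerebrovascular	binary	0/1	1..3	diagnosed cerebrovascular disease
coronary	binary	0/1	1..3	diagnosed coronary heart disease
diabetes	binary	0/1	1..3	diagnosed diabetes mellitus
cancer	binary	0/1	1..3	diagnosed cancer
support	integer	0..60	1..3	social support network score (higher = more support)
chew_group	ordinal	1..6	1..2	hardest food group the subject can bite and chew; 1 = toughest, 6 = softest
tils	integer	0..12	1..2	Three-Item Loneliness Scale total (items 0 = never .. 4 = always)
cesd	integer	0..22	1,3	11-item CES-D depressive-symptom score; >= 7 defines CSDS
observed	binary	0/1	all	1 = interviewed at this wave; monotone (no re-entry after dropout)
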