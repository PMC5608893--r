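quantity,numerator,denominator
major_bleeds_of_cohort,250,1361
intracranial_of_cohort,78,1361
gastrointestinal_of_cohort,97,1361
fatal_of_cohort,52,1361
bleeds_in_hasbled_high_of_bleeds,163,250
bleeds_in_hemorr2hages_high_of_bleeds,206,250
bleeds_in_atria_high_of_bleeds,74,250
bleeds_in_orbit_high_of_bleeds,85,250
hasbled_high_of_cohort,609,1361
hemorr2hages_high_of_cohort,1018,1361
orbit_high_of_cohort,319,1361
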