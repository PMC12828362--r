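study_id,n,events,cdmax_rep_gy_eqd2,chemo_fraction,interval_rep_months,followup_rep_months
Poltinnikov,9,0,82.2,0.333,13,5.5
Yamaguchi,12,6,93.8,1,8.5,4
Kim,10,3,98.7,0.3,15.6,4.9
Katano,4,1,88.2,0.833,17.4,8.8
Hong_2018,39,3,112,0.5,16,87
Zhou,55,11,115.2,NR,12,20
Chen,36,19,99.2,1,14.6,62
Kennedy,21,0,18.7,0,23,24
Schlampp,62,2,89.9,0.032,14,8.2
Schroder,30,0,81,0,14,13
Meijneke,8,0,85.2,0,17,12
Owen,18,0,62.5,0,18.4,21.2
Kilburn,33,1,69,0,18,17
Sumita,21,0,73,0.05,26.8,22.1
Binkley,38,1,44.1,0.237,16,17
Maranzano,18,0,45,0,18,57
Ho,27,0,84.8,0.48,29.5,11.2
Hong_2020,31,0,74.4,0.097,15.1,17.4
Ogawa,31,0,19.4,0,NR,26
Griffioen,1,1,120,NR,62,6
McAvoy,1,1,135.7,NR,36,29
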