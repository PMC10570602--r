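characteristic,group,depression,non_depression
gender,male,384,1284
gender,female,871,1348
residence,rural,950,1840
residence,urban,305,792
spouse_cohabitation,yes,982,2223
spouse_cohabitation,no,273,409
night_sleep_duration,lt6h,625,722
night_sleep_duration,ge6h,630,1910
recent_hospitalization,yes,235,296
recent_hospitalization,no,1020,2336
drinking_frequency,never,947,1682
drinking_frequency,lt_monthly,72,181
drinking_frequency,ge_monthly,236,769
smoking,yes,306,807
smoking,no,949,1825
chronic_disease,yes,713,1208
chronic_disease,no,542,1424
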