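id,sex,birth_year,birth_year_uncertainty,reproductive_status,pantgrunt_indegree,pantgrunt_outdegree
BB,male,1987,1,not_applicable,0.937,0.134
HW,male,1993,1,not_applicable,0.295,0.58
KT,male,1993,0,not_applicable,0,0.237
KU,female,1979,999,pregnant,0,0.231
KW,female,1981,999,nursing,0,0.609
ML,female,1975,999,cycling,0,0.407
MS,male,1991,0,not_applicable,0.313,0.299
NB,female,1962,999,cycling,0,0.691
NK,male,1982,1,not_applicable,2.224,0
RH,female,1965,999,nursing,0,0.21
SQ,male,1991,1,not_applicable,0.258,0.268
ZM,female,1968,999,cycling,0,0.361
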