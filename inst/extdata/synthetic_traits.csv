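species,n_queens,colony_size,brood_cycle,diet_seed,diet_insect,diet_liquid,diurnality,worker_size
sp001,polygynous,1414,seasonal,0.3131,0.6798,0.00710000000000011,diurnal,11.823
sp002,monogynous,44712,year_round,0.0328,0.6711,0.2961,non_diurnal,8.124
sp003,monogynous,891,seasonal,0.6097,0.3485,0.0418,non_diurnal,3.495
sp004,both,11530,seasonal,0.0156,0.5986,0.3858,diurnal,1.253
sp005,polygynous,63,seasonal,0.378,0.4027,0.2193,diurnal,4.488
sp006,polygynous,20011,seasonal,0.1272,0.4861,0.3867,diurnal,12.433
sp007,monogynous,61394,year_round,0.4221,0.5326,0.0453000000000001,non_diurnal,1.067
sp008,monogynous,623,seasonal,0.2216,0.3896,0.3888,non_diurnal,13.535
sp009,polygynous,22,year_round,0.1413,0.4078,0.4509,non_diurnal,10.688
sp010,polygynous,7574,seasonal,0.2708,0.4359,0.2933,diurnal,13.62
sp011,polygynous,37975,year_round,0.1235,0.5411,0.3354,non_diurnal,7.688
sp012,monogynous,26178,seasonal,0.2355,0.6129,0.1516,non_diurnal,8.814
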