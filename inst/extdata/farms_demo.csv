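farm_id,upazila_id,land_ha,pond_ha,head_age,head_education,head_female,n_members,dependency_ratio,off_farm_income,travel_time_city,production_costs_usd
f00001,u04,0,1.112303850057986,56,7,0,1,0.747,0,51.6,2339.286801547877
f00002,u08,0,0.7737177800171874,51,6,0,2,1.779,1,71.5,1349.6756637611572
f00003,u04,0,0.7833772564110357,45,2,0,7,0.623,0,51.8,1777.2853432817449
f00004,u02,0.10733853058968651,0.1535299229058793,60,6,0,5,0.393,0,76.5,478.0244877085013
f00005,u07,0.26192281497152203,0.24377441579921807,40,5,0,5,0.522,1,50.3,700.0448753594254
f00006,u02,0.8215448623623203,0.2814319636822334,56,4,0,5,0.802,1,35.9,2103.9305301802306
f00007,u04,0,0.8558177368095642,48,3,0,3,1.019,1,115.7,1739.782424797906
f00008,u10,0,1.0165441017851664,33,5,0,2,0.955,1,43.1,2063.2501666731205
f00009,u11,0.13071283187356358,0.3518440326704922,40,8,1,5,0.676,0,53.8,701.3303092862355
f00010,u11,0,0.5278464309456891,54,4,0,2,0.818,0,96.5,880.5278190102837
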