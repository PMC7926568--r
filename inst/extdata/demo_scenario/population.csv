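"age_cohort","gender","location","year","count"
"15-24","female","all",2020,2950000
"15-24","female","all",2021,3011950
"15-24","female","all",2022,3075201
"15-24","female","all",2023,3139780
"15-24","female","all",2024,3205716
"15-24","female","all",2025,3273036
"15-24","female","all",2026,3341769
"15-24","female","all",2027,3411946
"15-24","female","all",2028,3483597
"15-24","female","all",2029,3556753
"15-24","female","all",2030,3631445
"25-34","female","all",2020,2410000
"25-34","female","all",2021,2467840
"25-34","female","all",2022,2527068
"25-34","female","all",2023,2587718
"25-34","female","all",2024,2649823
"25-34","female","all",2025,2713419
"25-34","female","all",2026,2778541
"25-34","female","all",2027,2845226
"25-34","female","all",2028,2913511
"25-34","female","all",2029,2983435
"25-34","female","all",2030,3055038
"35-49","female","all",2020,1980000
"35-49","female","all",2021,2031480
"35-49","female","all",2022,2084298
"35-49","female","all",2023,2138490
"35-49","female","all",2024,2194091
"35-49","female","all",2025,2251137
"35-49","female","all",2026,2309667
"35-49","female","all",2027,2369718
"35-49","female","all",2028,2431331
"35-49","female","all",2029,2494546
"35-49","female","all",2030,2559404
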