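grade,metric,source,tss,df,ms,f,p
Severe,OA,Between Groups,14840.249,18,824.458,5.562,0.000
Severe,OA,Within Groups,14083.024,95,148.242,,
Severe,OA,Grand Total,28923.272,113,,,
Severe,kappa,Between Groups,5.895,18,0.328,5.430,0.000
Severe,kappa,Within Groups,5.730,95,0.060,,
Severe,kappa,Grand Total,11.625,113,,,
Severe,RE,Between Groups,1459.716,18,81.095,4.710,0.000
Severe,RE,Within Groups,1635.607,95,17.217,,
Severe,RE,Grand Total,3095.324,113,,,
High,OA,Between Groups,3454.562,18,191.920,3.550,0.000
High,OA,Within Groups,5136.480,95,54.068,,
High,OA,Grand Total,8591.042,113,,,
High,kappa,Between Groups,3.914,18,0.217,7.829,0.000
High,kappa,Within Groups,2.639,95,0.028,,
High,kappa,Grand Total,6.553,113,,,
High,RE,Between Groups,23.606,18,1.311,2.584,0.002
High,RE,Within Groups,48.222,95,0.508,,
High,RE,Grand Total,71.828,113,,,
Moderate,OA,Between Groups,6957.370,18,386.521,8.413,0.000
Moderate,OA,Within Groups,4364.848,95,45.946,,
Moderate,OA,Grand Total,11322.218,113,,,
Moderate,kappa,Between Groups,4.774,18,0.265,16.451,0.000
Moderate,kappa,Within Groups,1.531,95,0.016,,
Moderate,kappa,Grand Total,6.305,113,,,
Moderate,RE,Between Groups,2.998,18,0.167,4.671,0.000
Moderate,RE,Within Groups,3.387,95,0.036,,
Moderate,RE,Grand Total,6.385,113,,,
Slight,OA,Between Groups,11608.489,18,644.916,23.374,0.000
Slight,OA,Within Groups,2621.216,95,27.592,,
Slight,OA,Grand Total,14229.705,113,,,
Slight,kappa,Between Groups,4.392,18,0.244,26.617,0.000
Slight,kappa,Within Groups,0.871,95,0.009,,
Slight,kappa,Grand Total,5.262,113,,,
Slight,RE,Between Groups,1.785,18,0.099,13.981,0.000
Slight,RE,Within Groups,0.674,95,0.007,,
Slight,RE,Grand Total,2.459,113,,,
Non-desertification,OA,Between Groups,18799.030,18,1044.391,1.009,0.457
Non-desertification,OA,Within Groups,98285.865,95,1034.588,,
Non-desertification,OA,Grand Total,117084.895,113,,,
Non-desertification,kappa,Between Groups,5.465,18,0.304,1.750,0.044
Non-desertification,kappa,Within Groups,16.485,95,0.174,,
Non-desertification,kappa,Grand Total,21.950,113,,,
Non-desertification,RE,Between Groups,2.203,18,0.122,1.692,0.054
Non-desertification,RE,Within Groups,6.871,95,0.072,,
Non-desertification,RE,Grand Total,9.074,113,,,
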