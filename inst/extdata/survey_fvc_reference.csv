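image,fvc_percent,grade,oa_percent,kappa
1,4.3243,Severe,99.1168,0.9821
2,1.5050,Severe,99.011,0.9783
3,4.0864,Severe,99.6525,0.9922
4,3.3052,Severe,99.9252,0.9966
5,3.3717,Severe,98.7145,0.9642
6,2.8890,Severe,99.7404,0.9939
7,13.2679,High,98.9788,0.9671
8,18.3795,High,99.5751,0.9725
9,6.7185,High,99.5239,0.9879
10,16.2495,High,99.7815,0.9956
11,15.9524,High,99.54,0.9902
12,9.4557,High,98.8213,0.9764
13,32.6411,Moderate,99.8111,0.9676
14,43.2160,Moderate,99.9583,0.99
15,31.7365,Moderate,99.5985,0.9747
16,45.6735,Moderate,99.833,0.982
17,31.8236,Moderate,99.6005,0.9892
18,26.3766,Moderate,99.5415,0.9894
19,53.0043,Slight,99.5556,0.9855
20,55.3886,Slight,99.6876,0.9937
21,51.5241,Slight,99.931,0.9985
22,51.5331,Slight,99.8963,0.9928
23,54.7885,Slight,99.6876,0.9937
24,51.5424,Slight,99.9765,0.9946
25,86.2322,Non-desertification,99.874,0.9606
26,96.5132,Non-desertification,99.8873,0.9619
27,83.4444,Non-desertification,99.4857,0.9808
28,89.2501,Non-desertification,99.9279,0.9674
29,71.6581,Non-desertification,99.5638,0.9833
30,76.3327,Non-desertification,99.8111,0.9676
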