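age,qx
40,9e-04
41,0.000984756855334689
42,0.00107749562680963
43,0.00117896800565992
44,0.00128999647310431
45,0.00141148096694115
46,0.00154440617596637
47,0.00168984952133791
48,0.0018489898895795
49,0.00202311718800882
50,0.00221364280004125
51,0.00242211102511434
52,0.00265021159595897
53,0.00289979337467565
54,0.00317287933862884
55,0.00347168297762728
56,0.0037986262352969
57,0.0041563591400698
58,0.00454778128490748
59,0.0049760653298616
60,0.00544468271797165
61,0.00595743181293877
62,0.00651846868664491
63,0.00713234080606454
64,0.00780402389261711
65,0.00853896225272267
66,0.00934311290645866
67,0.0102229938720013
68,0.0111857369972198
69,0.0122391457666478
70,0.0133917585523855
71,0.0146529178216096
72,0.016032845861651
73,0.017542727636428
74,0.0191948014458242
75,0.0210024581228484
76,0.0229803495726164
77,0.0251445075329129
78,0.0275124735189452
79,0.0301034410055504
80,0.0329384109993102
81,0.036040362261558
82,0.0394344375620166
83,0.0431481474727373
84,0.0472115933541891
85,0.0516577113409016
86,0.0565225393042815
87,0.0618455089564618
88,0.0676697654628208
89,0.0740425171537815
90,0.0810154181704696
91,0.0886449871457517
92,0.0969930653142604
93,0.106127317764604
94,0.11612178189664
95,0.127057467529329
96,0.139023013523302
97,0.152115406240398
98,0.166440765663615
99,0.182115205549333
100,1
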