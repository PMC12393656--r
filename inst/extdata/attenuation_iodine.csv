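# mass attenuation (cm^2/g), iodine; kedge_keV=33.2
energy_keV,mu_rho_cm2_g
10.0,162.000000
11.0,125.724442
12.0,99.749468
13.0,80.621551
14.0,66.198337
15.0,55.100000
16.0,46.189636
17.0,39.136616
18.0,33.476218
19.0,28.877443
20.0,25.100000
21.0,22.052662
22.0,19.492334
23.0,17.324055
24.0,15.474452
25.0,13.886185
26.0,12.513982
27.0,11.321753
28.0,10.280480
29.0,9.366634
30.0,8.561000
31.0,7.851788
32.0,7.221130
33.0,6.658260
33.2,6.553000
33.2,35.800000
34.0,33.601150
35.0,31.105698
36.0,28.858247
37.0,26.828253
38.0,24.989621
39.0,23.319965
40.0,21.800000
41.0,20.465878
42.0,19.242664
43.0,18.118818
44.0,17.084229
45.0,16.130014
46.0,15.248346
47.0,14.432308
48.0,13.675769
49.0,12.973283
50.0,12.320000
51.0,11.686739
52.0,11.097394
53.0,10.548160
54.0,10.035627
55.0,9.556729
56.0,9.108705
57.0,8.689066
58.0,8.295562
59.0,7.926156
60.0,7.579000
61.0,7.251099
62.0,6.942375
63.0,6.651424
64.0,6.376965
65.0,6.117827
66.0,5.872938
67.0,5.641317
68.0,5.422061
69.0,5.214344
70.0,5.017404
71.0,4.830539
72.0,4.653103
73.0,4.484500
74.0,4.324176
75.0,4.171622
76.0,4.026365
77.0,3.887967
78.0,3.756021
79.0,3.630149
80.0,3.510000
81.0,3.396226
82.0,3.287469
83.0,3.183450
84.0,3.083909
85.0,2.988605
86.0,2.897309
87.0,2.809810
88.0,2.725909
89.0,2.645418
90.0,2.568165
91.0,2.493984
92.0,2.422722
93.0,2.354233
94.0,2.288383
95.0,2.225042
96.0,2.164091
97.0,2.105415
98.0,2.048908
99.0,1.994468
100.0,1.942000
101.0,1.895252
102.0,1.850073
103.0,1.806396
104.0,1.764158
105.0,1.723297
106.0,1.683757
107.0,1.645482
108.0,1.608422
109.0,1.572526
110.0,1.537749
111.0,1.504045
112.0,1.471372
113.0,1.439690
114.0,1.408960
115.0,1.379146
116.0,1.350213
117.0,1.322127
118.0,1.294858
119.0,1.268374
120.0,1.242646
121.0,1.217647
122.0,1.193351
123.0,1.169732
124.0,1.146766
125.0,1.124430
126.0,1.102702
127.0,1.081561
128.0,1.060986
129.0,1.040958
130.0,1.021459
131.0,1.002470
132.0,0.983974
133.0,0.965955
134.0,0.948398
135.0,0.931287
136.0,0.914607
137.0,0.898345
138.0,0.882487
139.0,0.867021
140.0,0.851934
141.0,0.837214
142.0,0.822849
143.0,0.808829
144.0,0.795144
145.0,0.781782
146.0,0.768734
147.0,0.755991
148.0,0.743544
149.0,0.731383
150.0,0.719500
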