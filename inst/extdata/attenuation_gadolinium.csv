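# mass attenuation (cm^2/g), gadolinium; kedge_keV=50.2
energy_keV,mu_rho_cm2_g
10.0,109.300000
11.0,86.750533
12.0,70.252470
13.0,57.861283
14.0,48.346267
15.0,40.900000
16.0,34.606304
17.0,29.579306
18.0,25.510454
19.0,22.178092
20.0,19.420000
21.0,17.121725
22.0,15.184169
23.0,13.537965
24.0,12.129340
25.0,10.916139
26.0,9.864982
27.0,8.949180
28.0,8.147216
29.0,7.441597
30.0,6.818000
31.0,6.244042
32.0,5.734391
33.0,5.280156
34.0,4.873896
35.0,4.509347
36.0,4.181213
37.0,3.884991
38.0,3.616836
39.0,3.373452
40.0,3.152000
41.0,2.959428
42.0,2.782845
43.0,2.620590
44.0,2.471206
45.0,2.333414
46.0,2.206084
47.0,2.088222
48.0,1.978943
49.0,1.877462
50.0,1.783080
50.2,1.765000
50.2,9.362000
51.0,8.990011
52.0,8.553309
53.0,8.145543
54.0,7.764303
55.0,7.407419
56.0,7.072933
57.0,6.759077
58.0,6.464249
59.0,6.186996
60.0,5.926000
61.0,5.654517
62.0,5.399586
63.0,5.159957
64.0,4.934488
65.0,4.722142
66.0,4.521969
67.0,4.333103
68.0,4.154751
69.0,3.986185
70.0,3.826738
71.0,3.675796
72.0,3.532797
73.0,3.397219
74.0,3.268584
75.0,3.146450
76.0,3.030408
77.0,2.920079
78.0,2.815114
79.0,2.715188
80.0,2.620000
81.0,2.536857
82.0,2.457324
83.0,2.381204
84.0,2.308312
85.0,2.238475
86.0,2.171531
87.0,2.107328
88.0,2.045725
89.0,1.986589
90.0,1.929794
91.0,1.875224
92.0,1.822769
93.0,1.772325
94.0,1.723794
95.0,1.677084
96.0,1.632110
97.0,1.588789
98.0,1.547045
99.0,1.506805
100.0,1.468000
101.0,1.433253
102.0,1.399658
103.0,1.367167
104.0,1.335734
105.0,1.305314
106.0,1.275865
107.0,1.247348
108.0,1.219724
109.0,1.192959
110.0,1.167017
111.0,1.141867
112.0,1.117477
113.0,1.093818
114.0,1.070861
115.0,1.048581
116.0,1.026951
117.0,1.005947
118.0,0.985547
119.0,0.965727
120.0,0.946466
121.0,0.927745
122.0,0.909543
123.0,0.891843
124.0,0.874626
125.0,0.857876
126.0,0.841577
127.0,0.825712
128.0,0.810268
129.0,0.795229
130.0,0.780582
131.0,0.766314
132.0,0.752413
133.0,0.738866
134.0,0.725661
135.0,0.712788
136.0,0.700236
137.0,0.687994
138.0,0.676053
139.0,0.664404
140.0,0.653036
141.0,0.641942
142.0,0.631113
143.0,0.620540
144.0,0.610216
145.0,0.600134
146.0,0.590286
147.0,0.580665
148.0,0.571265
149.0,0.562079
150.0,0.553100
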