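# synthetic dihedral observations (aryl_alkyl chemotype)
PATTERN [c:1][c:2][C:3][C:4]
-90.1430
-179.1240
-163.4521
-3.7458
177.6607
83.7968
-91.4622
89.9543
-9.0524
-99.5172
-98.9981
-99.4109
-88.2443
89.8622
-5.5657
101.8932
168.5900
102.0889
100.7426
-74.0227
-177.2636
5.1230
-86.7890
90.0108
170.5194
77.9113
-80.0363
-76.2179
-101.7120
113.1566
-100.7226
1.8133
-8.1169
93.1519
82.0714
-88.3739
89.3459
10.3223
87.7106
93.8012
81.0197
98.2797
-90.1687
83.5057
98.1126
78.0342
92.0851
-94.4224
-178.3630
88.8326
89.5659
-93.9065
65.2766
171.9964
179.6293
-88.4224
91.1241
-165.0450
-96.6479
112.5370
13.3209
-106.1937
84.9772
173.4102
61.4842
-100.5828
-105.5028
174.9977
-177.4800
-96.3571
-80.2015
99.6997
93.4462
-104.6071
-59.9530
177.5470
-0.8093
90.0545
85.6651
-76.0912
-97.6201
89.2589
17.6771
-91.0175
79.2506
97.1081
-167.7005
4.0414
-75.9819
178.1375
69.3115
0.2736
84.3576
86.0969
-179.0366
-81.0536
-81.3678
164.2345
-105.4982
-4.8417
-6.6036
-94.5292
-78.4947
172.4124
97.3184
-85.2473
-92.8722
94.2392
10.3923
89.7679
-84.7682
-73.6009
178.7148
98.5228
90.0106
95.7809
94.3631
-98.7277
-87.1908
-76.1383
94.3955
175.0444
-71.1334
-162.8371
90.7115
-84.3134
-90.6439
104.6382
117.0109
94.9114
-6.5517
-70.6454
-102.1980
10.0423
-3.2302
82.7058
-77.4888
97.6110
7.9556
-6.8891
-169.1249
97.5135
-99.4732
-1.5331
-101.9786
-90.9280
-169.8076
82.0408
-90.2484
-84.2047
-94.9885
168.7447
72.2570
-110.7314
108.7668
-12.3413
-6.2190
81.3490
-99.9955
-179.6463
-94.2543
105.9976
-9.6922
81.9639
0.4231
79.1789
14.7047
80.8176
93.6623
-92.2218
105.2376
-97.9921
-177.7126
-19.4275
94.8683
-87.9743
-101.0225
-85.9294
177.8231
88.2318
-2.7324
-87.4954
86.4982
91.2289
74.3270
101.4371
-88.5964
-91.3895
-91.1293
101.9919
-92.6799
95.3038
176.6060
-102.1617
95.4838
86.8007
3.6719
-89.9026
-93.4078
169.1322
-85.5560
-93.4376
91.8452
24.3459
178.4083
86.1233
7.8100
93.1025
91.6392
154.7699
8.4099
-93.6268
177.8812
95.0853
165.2716
76.2719
111.4628
-71.0538
-88.4279
-91.3047
-20.3090
76.5823
177.4275
-72.7751
-68.4875
-96.5445
-86.1035
-99.8282
-177.5037
-69.8711
102.3593
78.9593
-7.8892
-177.8885
-14.1528
-173.7214
170.4687
3.3467
-78.5385
93.7688
100.6992
-100.4810
-167.2687
111.0938
103.4643
83.4145
-91.8390
-99.8138
-105.1855
-2.1596
-152.6857
-174.2942
-76.7916
90.9952
86.0565
96.3649
-24.8557
-2.3188
79.8214
-77.1237
73.5319
-102.7033
-86.1270
-173.4118
-113.8643
167.9766
81.0230
-99.0336
-8.8801
-91.9507
-68.3250
3.8586
-88.6398
83.3537
-177.7256
93.6456
-76.8187
-4.9053
83.5988
174.6978
95.0092
86.0900
85.7030
-13.5011
-90.2140
93.7698
-92.1635
-5.9099
8.4167
0.7595
95.4061
76.8120
-98.3790
1.0660
84.9468
-94.7824
-90.9438
9.6048
-81.5159
91.3749
0.1943
93.0986
-74.2874
105.6624
173.5998
-80.2034
94.3818
-2.1961
-80.1059
0.6653
91.6992
-63.1895
4.8729
-77.8900
-15.9833
79.6695
90.8930
-83.5362
99.0549
-86.0277
97.7376
-179.1010
-178.5980
70.2194
-177.3984
81.6381
88.6134
93.1119
-91.6487
-77.9495
175.8398
-3.4157
-178.3994
-0.4081
-179.6463
-88.5073
-98.2732
89.0237
76.5156
165.8128
-84.6724
96.4126
103.3413
-90.6528
170.1831
87.5035
-70.4913
84.2895
120.3616
4.2411
15.8117
93.7269
169.4313
96.6907
175.2209
88.5295
-93.7766
79.2926
114.7541
85.0455
-105.3237
6.4135
79.8320
-83.8868
-73.5354
175.9268
-87.4428
-86.6036
-176.3828
166.9634
-83.4497
89.1314
100.7110
173.3422
-75.4022
85.1897
90.1259
77.6554
-88.3393
178.2376
-7.2220
82.6816
111.7781
82.3998
81.7871
-174.2822
86.0559
-85.7522
89.8508
22.3410
0.3508
-107.2542
99.3126
98.2693
-91.3333
92.2175
-91.3089
89.1654
-98.0138
95.3559
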