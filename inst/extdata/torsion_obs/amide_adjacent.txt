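# synthetic dihedral observations (amide_adjacent chemotype)
PATTERN [C:1][C:2][N:3][C:4]
178.3490
-178.9775
171.2028
-171.0745
171.2865
177.3007
-179.6212
179.0282
172.3981
163.3468
174.9495
-157.5910
-68.8689
-83.6517
76.6342
-179.9794
-174.8145
169.4322
171.1150
178.4738
166.1284
178.9510
-171.4085
-176.5908
-170.2945
73.1024
77.8441
78.1881
-179.1916
81.1571
172.9994
78.2199
-178.2576
170.9887
-167.5541
70.0609
-176.9932
83.2983
-81.5858
177.2183
-86.0694
-176.1003
-171.8628
89.0360
-171.2056
171.4899
176.2855
-178.2245
-168.2287
174.8885
-88.6312
-76.5000
-170.4146
173.8712
83.0910
-174.8110
-78.3507
-173.9350
177.3746
178.2021
173.6303
176.4163
-78.8051
-177.6577
-85.1247
173.1048
-174.8316
81.4798
-170.7330
-157.3783
179.3828
179.7827
176.6877
-68.7149
85.5446
-175.5599
168.1843
-178.9394
-175.3896
179.8324
-172.9599
-167.8659
85.2570
-79.4723
-160.4981
176.2896
169.7312
-177.8189
174.9187
72.9316
179.6200
-178.0181
92.1003
172.2546
174.6230
178.7880
178.7566
-159.4196
166.5148
167.8116
-175.3083
170.8503
177.0928
-170.9996
-73.7924
77.5523
-175.7562
75.1643
-83.6284
177.0917
178.1425
170.7963
-172.0372
179.7704
163.0153
169.3468
73.2289
-178.2123
165.9815
-76.0874
84.8601
-87.9834
-67.3642
71.1153
-66.3520
179.7661
171.0979
170.6350
176.3821
80.4059
-175.4312
175.5964
173.6518
172.7066
173.5847
175.1232
179.4315
-171.7745
-172.4264
175.7747
175.7900
85.0705
-173.2194
-167.3437
170.0722
-173.8707
-78.0993
82.9830
176.9789
171.1142
179.6132
167.2655
-76.7540
75.3101
-87.6675
87.6526
-179.1714
-70.6370
-177.1992
-172.8234
78.3972
170.7384
84.5141
-168.0616
-85.2265
-174.8312
80.1316
-173.9148
-173.4983
-74.9076
-79.6721
-178.6990
177.5660
171.7772
171.2864
-172.0593
170.2018
-179.4421
172.5623
165.6593
-69.6484
-170.9603
176.4209
166.3450
92.1231
79.0075
-164.2473
-167.7427
176.4509
-176.2773
176.5811
-83.0130
-178.9314
172.2356
89.7723
-89.6582
171.5487
83.9579
173.8380
-165.8482
-70.7940
76.1664
-88.7029
92.9331
-173.8794
78.7881
176.9493
-169.9024
-79.3757
175.6330
78.8589
83.0855
-173.9307
-176.9521
-170.3186
160.2035
179.7125
-76.9023
67.1243
-166.1471
-173.8495
-75.5953
71.6275
-89.1364
-78.6393
-177.6608
173.9027
-173.9397
-176.9821
-85.2453
-98.1167
-177.4205
88.4946
85.6968
173.5155
-68.8680
-179.6923
-177.1108
70.1662
-80.1437
173.5375
-168.7756
-175.3964
-177.7011
176.1702
172.5279
-70.5262
-83.2796
169.3518
-175.5893
-162.3340
178.5780
-72.9399
173.3384
-164.2333
83.1859
-167.7628
-172.7659
176.8082
-85.2994
76.8441
92.8314
175.1593
85.9467
-170.6862
179.0235
-165.9969
75.4500
71.4357
95.9932
169.2398
87.5747
92.3300
179.5168
78.1985
-170.2559
169.8504
76.1470
174.4314
-168.8403
92.5214
-168.7282
171.3922
-84.7564
174.3026
-177.4947
177.4600
-179.9470
-69.4850
-170.9619
-163.9772
179.4000
179.7107
71.7513
64.2711
163.7316
70.9410
174.4774
-88.8494
87.2959
-179.1365
-173.6329
79.4196
-171.9877
172.2766
171.8450
-163.8052
-178.2421
177.4342
-179.8371
177.2652
-176.7869
175.1880
165.6315
174.7591
-178.3925
-169.7233
175.2798
174.2535
-84.6246
175.6577
-176.1963
176.0944
-78.1743
-81.7735
-175.0735
-173.5373
176.5319
-173.4999
-170.0254
-73.3889
89.5547
-81.7580
64.4249
-103.5335
-171.4109
-172.1097
166.9953
173.7477
70.0586
176.3555
168.4260
-178.5146
-178.7354
-179.5741
176.3041
172.5825
70.0429
70.1024
85.2633
176.3139
-172.4611
-84.3119
93.1526
176.0201
-66.9358
79.3972
172.0668
179.7907
-177.2777
-169.6535
-175.1863
-177.9969
-74.9392
-168.7304
-89.0155
176.5202
-179.5042
-175.0930
175.2990
169.5261
-171.3739
171.1293
178.1342
-171.7228
-80.1079
179.4789
-173.8689
76.5053
-75.8555
74.2780
173.7107
-81.0017
-62.9869
-165.3040
-161.8892
175.3058
176.3005
-73.6433
-178.8582
-179.9064
73.2812
178.2536
166.0715
170.3481
-69.3789
177.6102
74.4043
-75.5685
68.8446
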