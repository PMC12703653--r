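# synthetic dihedral observations (alkyl chemotype)
PATTERN [C:1][C:2][C:3][C:4]
-179.2572
163.7710
-52.1275
-179.6009
179.5092
177.9922
62.6628
178.3630
75.4390
-176.4262
70.1520
-65.4681
65.3452
170.1426
-61.8503
62.7118
-77.5261
179.7487
75.5531
60.5310
61.9416
-56.8029
169.4616
-78.3837
177.3197
173.7250
-178.6153
170.6309
173.3995
173.3003
-178.5099
71.2388
169.3164
70.8153
61.1274
-172.8266
173.6603
56.8632
-59.7204
-179.5961
-69.5174
-70.5649
178.3943
176.1155
-169.8228
-175.7116
175.9975
174.3749
-173.6033
-53.4163
174.4468
174.6511
175.2922
169.9936
175.8187
-179.2054
59.5599
173.1050
61.8977
60.9495
53.2692
-178.0433
173.1604
-46.3214
179.4326
-71.1833
177.1639
-165.7824
64.5815
166.6915
72.5124
-178.2921
60.3358
-176.3270
174.7354
175.0565
177.0983
167.8765
63.9093
174.9888
-73.5274
-177.8984
-174.5898
177.3752
-173.9130
-175.0402
170.7239
-75.9303
-67.7600
178.9498
165.0314
-169.4113
61.8288
173.7639
-165.5939
-179.5791
-57.5849
-171.9681
172.3882
175.1202
70.2584
-171.7095
64.6585
-177.6525
176.4523
55.3953
-174.2421
74.0284
170.0084
-160.7123
-57.4157
173.9562
175.7596
179.0058
48.0450
-177.0695
-166.6329
-172.7255
173.6364
177.3964
-179.3979
172.5743
177.7249
178.6149
168.7643
-179.7354
58.3708
-59.3291
66.3114
59.3560
-73.0586
-81.2271
169.6298
176.0552
176.4768
178.6288
-177.7173
162.9055
-54.4678
60.4481
174.8383
-178.3378
-62.2199
177.1175
-168.3649
-177.5289
172.5932
55.7125
61.2521
63.4196
58.1821
-178.2126
178.2689
174.6321
170.9110
66.1232
-177.8711
75.1079
-175.5926
-173.0607
177.4917
-170.1460
-162.0605
-59.8524
179.6673
172.3730
178.4496
-59.7165
63.0317
-177.5656
179.4107
-66.8560
-179.0787
171.1868
173.3760
66.2065
174.4319
67.5796
-174.2182
173.9239
-179.8672
-168.4032
179.8613
-170.7841
-174.1433
-173.2426
-170.6968
172.2327
63.8580
-75.4567
177.3879
73.6682
-165.8797
-171.4051
-178.8900
-172.5441
-168.3598
177.9471
-58.1705
177.1621
59.8128
-175.4992
171.0314
-178.3938
176.5090
177.0304
-170.3263
-177.0669
177.1066
-178.7738
-174.7174
175.2764
-171.0491
170.8593
59.0659
64.0266
62.1910
-175.0167
-165.9993
174.5516
171.5183
-177.9841
173.6664
-68.1800
-59.8292
-53.1608
-173.5584
-70.7954
178.3506
-179.2323
62.4533
177.2960
175.2389
175.5581
172.2429
177.3575
-76.4417
162.7436
74.1706
77.1161
-61.5257
-177.0368
-71.1743
-172.1192
173.2222
177.8266
179.2467
-173.5412
178.7424
58.3828
-176.1826
176.7675
-77.5189
-174.9165
-61.9705
62.8536
173.9505
179.7823
177.6266
70.3171
173.6660
178.3878
177.3828
179.7815
174.9037
-177.0377
77.1072
-163.5213
178.7756
175.3643
62.6511
179.4897
-177.3777
-172.6901
-172.4238
-69.1224
-55.1934
-178.3758
-168.6699
-177.7306
-176.6138
-69.8823
-174.5961
-55.8206
171.7673
61.9316
61.2153
-170.1263
-75.3216
-61.5592
167.5250
173.9598
68.5098
-68.5259
-70.9726
178.5974
61.4613
173.9935
53.6211
44.0395
178.5354
177.8224
-63.7930
62.4446
-179.8840
178.8085
64.1065
63.4658
-62.8029
179.6887
56.7388
-64.4325
69.1319
-44.9262
-170.7780
175.2898
-173.6284
171.7559
67.6755
59.4336
162.7902
177.1609
-177.9294
175.8425
-68.1578
78.0241
160.3247
-174.2637
170.4423
178.6245
-66.6425
58.3125
-173.4262
68.1186
169.9331
-61.7140
76.8370
-167.6628
-171.7354
170.4986
179.7545
-177.4026
64.2545
-78.0891
179.8858
-178.8195
-173.3987
-169.4596
58.9739
166.5898
-70.1039
48.8138
-63.5196
166.2368
175.9945
-164.8507
179.9850
51.9998
54.9002
173.4207
68.3672
-172.3821
-168.6198
57.8494
-67.1330
-65.6042
70.9332
-177.1465
58.8743
-67.6842
-66.2342
-175.0809
-179.0555
173.8187
168.0127
63.4439
-68.5008
-179.0098
-167.8233
-171.4561
178.0783
-56.0806
174.0262
82.2467
165.4751
175.3163
-56.0090
172.4334
78.8236
-175.7858
-176.7258
166.8568
60.1688
60.2244
179.6328
70.3821
175.5752
-174.0293
173.0998
-68.1533
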