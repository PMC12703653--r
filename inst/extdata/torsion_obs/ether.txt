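# synthetic dihedral observations (ether chemotype)
PATTERN [C:1][C:2][O:3][C:4]
178.6877
168.9338
-71.6119
-81.3239
-170.3206
-172.8439
-75.8096
-177.6230
-73.4216
-76.2559
87.2926
-92.3414
-70.2124
75.3449
-169.6398
-69.3496
77.7644
179.3608
-176.3615
-169.7900
-64.8813
77.1540
179.0356
-68.6378
70.8878
71.7473
-170.2422
-179.3303
-175.2808
-79.1394
-173.8443
-173.5842
174.4251
-170.5772
-70.3132
71.2648
-176.9148
70.7232
-171.5467
73.3513
-175.1439
175.6155
58.2002
-177.9935
179.5604
174.7222
168.3531
75.1898
79.3833
173.5288
178.0878
177.1751
-68.4432
-77.7622
170.5369
66.7494
-75.6007
-68.3713
-83.2879
-76.1772
72.7484
64.0105
-62.5324
70.4004
92.4987
-68.6457
-178.3795
179.8236
77.4362
66.1260
-173.8762
74.8238
-82.2320
78.2000
65.8057
-178.4947
-178.2617
171.6073
-75.6010
62.4561
-84.3904
57.8136
77.7337
82.2398
-171.2281
63.2299
177.7552
-173.2309
169.7127
177.5005
-77.9027
86.2996
-77.0416
-176.9039
-175.8005
79.9212
177.3375
-174.0374
177.5099
178.1260
170.6731
178.0816
-170.5249
76.6601
-75.3491
172.2314
-175.4062
169.9211
83.4934
71.5281
-178.0866
175.9814
-88.6310
79.1902
87.5134
55.2700
73.8094
-58.1133
177.2304
-67.1425
-176.8685
175.9200
171.6028
-74.6319
171.9294
69.7500
-74.2479
-179.8566
-87.8282
-176.1354
-76.7954
176.5008
-169.3779
176.2522
-85.7197
-166.6765
-175.6884
82.9951
-177.2681
-83.4690
74.6672
169.6574
67.8491
-175.6647
82.7571
178.0401
-173.1186
-80.4068
175.9997
-165.3437
177.3658
-177.9095
-83.8973
83.4977
-178.3600
163.8054
-65.1810
84.5628
-173.8199
63.7237
71.5406
-78.5383
85.7919
-83.5971
177.3193
81.0067
-164.0223
89.3353
170.1362
-100.4177
-83.6787
75.4861
-76.4541
-72.2695
83.8543
80.5105
78.7679
61.8795
69.5678
-71.1095
76.8094
69.8266
179.0937
-175.8358
-159.3061
-175.6625
-171.4784
173.9988
-68.6497
174.0019
-177.5496
-169.4530
177.8677
-177.8736
84.1187
172.1076
-80.3893
59.7620
174.2566
176.9317
-77.5643
-91.7354
165.1853
-176.4827
76.1352
173.3995
64.0306
-179.8009
87.6479
173.9223
175.6916
72.9177
-80.1568
-170.2780
-165.7440
-75.5123
-175.0042
-82.5088
60.3385
172.7881
172.3928
173.3176
-175.6312
-167.0997
174.7751
179.7068
74.1149
-170.0640
69.4606
65.6765
171.5513
-174.2121
-177.1182
-72.9502
-173.9769
-82.9410
-168.1094
174.1868
75.7732
-178.2811
-175.8522
72.6296
177.1840
-178.9302
178.1851
-173.0954
-167.1663
176.4333
-84.5166
-178.0270
173.9081
176.8481
166.1739
77.1035
167.0753
-75.9382
77.6074
59.7925
176.2416
-179.0092
170.9837
-78.2144
-74.9588
-174.6197
168.4291
65.8510
177.5934
-86.1113
58.7802
79.0417
-173.8280
-87.9031
84.1394
-163.2137
73.6611
177.8646
81.3586
-78.6548
172.2264
176.2197
-172.4188
-171.8717
-165.9851
-171.6184
176.9771
-175.9352
-83.5615
-76.1538
-83.0936
-170.0558
179.3689
68.5416
-82.9696
68.1334
172.3941
171.0256
178.9194
68.0074
-177.9306
166.0389
169.8211
174.6954
-77.3723
175.4083
179.7906
-72.9222
79.2673
-79.3365
-177.2987
178.0967
-170.9944
76.6375
-75.1270
-178.5184
75.8658
80.3919
172.3843
176.0122
-80.2281
-76.0086
-80.1029
-177.2995
-75.2346
-65.1702
-167.3178
72.4850
-172.1940
-69.0633
-162.1963
-86.9787
83.8486
70.7735
-168.9919
172.7807
178.4978
173.0372
-178.0595
-65.2534
172.1582
-175.5233
-69.2368
60.7869
-178.2076
170.8801
86.0152
89.2409
77.3524
172.5468
-69.9151
-81.6866
66.8408
-178.7082
-174.9574
179.7640
-179.9015
-77.3323
88.6445
-86.7454
-178.1212
175.9274
58.0701
-175.4885
-165.6877
-179.5744
-67.6969
-76.1721
-76.4096
-83.4443
-65.0874
84.0226
174.5159
-60.9676
-177.7126
-75.7699
-175.7117
69.3214
-177.7888
77.4603
68.3900
-176.4373
-79.3961
168.4561
-76.7983
-177.5877
76.3964
-79.6627
-76.8320
-172.0369
-174.3796
66.4471
179.0750
-174.4606
166.6244
76.2820
68.8025
-74.0758
171.6882
-178.5795
-166.4891
-170.5712
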