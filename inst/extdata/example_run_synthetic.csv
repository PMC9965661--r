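bottle_id,role,material_id,replicate,day,bod_mg_l
BLK-1,blank,BLANK,1,0,0
BLK-1,blank,BLANK,1,1,0.683
BLK-1,blank,BLANK,1,2,0.45
BLK-1,blank,BLANK,1,3,1.29
BLK-1,blank,BLANK,1,4,0.88
BLK-1,blank,BLANK,1,5,0.898
BLK-1,blank,BLANK,1,6,0.983
BLK-1,blank,BLANK,1,7,0.726
BLK-1,blank,BLANK,1,8,0.589
BLK-1,blank,BLANK,1,9,0.445
BLK-1,blank,BLANK,1,10,0.585
BLK-1,blank,BLANK,1,11,0.788
BLK-1,blank,BLANK,1,12,0.975
BLK-1,blank,BLANK,1,13,1.257
BLK-1,blank,BLANK,1,14,0.787
BLK-1,blank,BLANK,1,15,1.195
BLK-1,blank,BLANK,1,16,1.072
BLK-1,blank,BLANK,1,17,1.024
BLK-1,blank,BLANK,1,18,1.117
BLK-1,blank,BLANK,1,19,1.23
BLK-1,blank,BLANK,1,20,0.936
BLK-1,blank,BLANK,1,21,0.47
BLK-1,blank,BLANK,1,22,0.352
BLK-1,blank,BLANK,1,23,0.812
BLK-1,blank,BLANK,1,24,0.874
BLK-1,blank,BLANK,1,25,1.22
BLK-1,blank,BLANK,1,26,0.465
BLK-1,blank,BLANK,1,27,1.584
BLK-1,blank,BLANK,1,28,0.968
BLK-2,blank,BLANK,2,0,0
BLK-2,blank,BLANK,2,1,1.014
BLK-2,blank,BLANK,2,2,1.17
BLK-2,blank,BLANK,2,3,0.769
BLK-2,blank,BLANK,2,4,0.637
BLK-2,blank,BLANK,2,5,1.105
BLK-2,blank,BLANK,2,6,0.693
BLK-2,blank,BLANK,2,7,1.298
BLK-2,blank,BLANK,2,8,1.084
BLK-2,blank,BLANK,2,9,1.231
BLK-2,blank,BLANK,2,10,1.427
BLK-2,blank,BLANK,2,11,1.511
BLK-2,blank,BLANK,2,12,1.345
BLK-2,blank,BLANK,2,13,0.916
BLK-2,blank,BLANK,2,14,0.862
BLK-2,blank,BLANK,2,15,0.601
BLK-2,blank,BLANK,2,16,0.769
BLK-2,blank,BLANK,2,17,0.548
BLK-2,blank,BLANK,2,18,0.631
BLK-2,blank,BLANK,2,19,1.208
BLK-2,blank,BLANK,2,20,0.837
BLK-2,blank,BLANK,2,21,1.145
BLK-2,blank,BLANK,2,22,1.09
BLK-2,blank,BLANK,2,23,1.167
BLK-2,blank,BLANK,2,24,0.623
BLK-2,blank,BLANK,2,25,1
BLK-2,blank,BLANK,2,26,1.031
BLK-2,blank,BLANK,2,27,1.101
BLK-2,blank,BLANK,2,28,0.421
CPLUS-1,positive_control,CPLUS,1,0,0
CPLUS-1,positive_control,CPLUS,1,1,5.529
CPLUS-1,positive_control,CPLUS,1,2,13.004
CPLUS-1,positive_control,CPLUS,1,3,20.2
CPLUS-1,positive_control,CPLUS,1,4,27.589
CPLUS-1,positive_control,CPLUS,1,5,35.646
CPLUS-1,positive_control,CPLUS,1,6,42.259
CPLUS-1,positive_control,CPLUS,1,7,48.446
CPLUS-1,positive_control,CPLUS,1,8,54.258
CPLUS-1,positive_control,CPLUS,1,9,58.985
CPLUS-1,positive_control,CPLUS,1,10,64.722
CPLUS-1,positive_control,CPLUS,1,11,68.288
CPLUS-1,positive_control,CPLUS,1,12,71.326
CPLUS-1,positive_control,CPLUS,1,13,75.785
CPLUS-1,positive_control,CPLUS,1,14,78.547
CPLUS-1,positive_control,CPLUS,1,15,81.217
CPLUS-1,positive_control,CPLUS,1,16,83.749
CPLUS-1,positive_control,CPLUS,1,17,86.332
CPLUS-1,positive_control,CPLUS,1,18,88.313
CPLUS-1,positive_control,CPLUS,1,19,90.161
CPLUS-1,positive_control,CPLUS,1,20,92.392
CPLUS-1,positive_control,CPLUS,1,21,94.373
CPLUS-1,positive_control,CPLUS,1,22,95.682
CPLUS-1,positive_control,CPLUS,1,23,96.839
CPLUS-1,positive_control,CPLUS,1,24,98.74
CPLUS-1,positive_control,CPLUS,1,25,99.339
CPLUS-1,positive_control,CPLUS,1,26,101.253
CPLUS-1,positive_control,CPLUS,1,27,102.023
CPLUS-1,positive_control,CPLUS,1,28,102.769
CPLUS-2,positive_control,CPLUS,2,0,0
CPLUS-2,positive_control,CPLUS,2,1,5.215
CPLUS-2,positive_control,CPLUS,2,2,12.596
CPLUS-2,positive_control,CPLUS,2,3,20.491
CPLUS-2,positive_control,CPLUS,2,4,27.963
CPLUS-2,positive_control,CPLUS,2,5,35.067
CPLUS-2,positive_control,CPLUS,2,6,42.269
CPLUS-2,positive_control,CPLUS,2,7,48.113
CPLUS-2,positive_control,CPLUS,2,8,54.214
CPLUS-2,positive_control,CPLUS,2,9,59.584
CPLUS-2,positive_control,CPLUS,2,10,64.404
CPLUS-2,positive_control,CPLUS,2,11,67.443
CPLUS-2,positive_control,CPLUS,2,12,71.348
CPLUS-2,positive_control,CPLUS,2,13,75.29
CPLUS-2,positive_control,CPLUS,2,14,77.981
CPLUS-2,positive_control,CPLUS,2,15,81.013
CPLUS-2,positive_control,CPLUS,2,16,83.933
CPLUS-2,positive_control,CPLUS,2,17,86.417
CPLUS-2,positive_control,CPLUS,2,18,88.225
CPLUS-2,positive_control,CPLUS,2,19,90.569
CPLUS-2,positive_control,CPLUS,2,20,92.036
CPLUS-2,positive_control,CPLUS,2,21,94.169
CPLUS-2,positive_control,CPLUS,2,22,95.466
CPLUS-2,positive_control,CPLUS,2,23,97.643
CPLUS-2,positive_control,CPLUS,2,24,98.573
CPLUS-2,positive_control,CPLUS,2,25,99.84
CPLUS-2,positive_control,CPLUS,2,26,100.722
CPLUS-2,positive_control,CPLUS,2,27,101.681
CPLUS-2,positive_control,CPLUS,2,28,103.155
ID016-1,sample,ID016,1,0,0
ID016-1,sample,ID016,1,1,1.371
ID016-1,sample,ID016,1,2,3.174
ID016-1,sample,ID016,1,3,4.078
ID016-1,sample,ID016,1,4,5.713
ID016-1,sample,ID016,1,5,6.414
ID016-1,sample,ID016,1,6,8.292
ID016-1,sample,ID016,1,7,9.157
ID016-1,sample,ID016,1,8,10.583
ID016-1,sample,ID016,1,9,11.043
ID016-1,sample,ID016,1,10,12.195
ID016-1,sample,ID016,1,11,12.686
ID016-1,sample,ID016,1,12,13.495
ID016-1,sample,ID016,1,13,13.989
ID016-1,sample,ID016,1,14,14.221
ID016-1,sample,ID016,1,15,14.984
ID016-1,sample,ID016,1,16,15.797
ID016-1,sample,ID016,1,17,15.766
ID016-1,sample,ID016,1,18,16.748
ID016-1,sample,ID016,1,19,16.578
ID016-1,sample,ID016,1,20,17.36
ID016-1,sample,ID016,1,21,17.596
ID016-1,sample,ID016,1,22,17.304
ID016-1,sample,ID016,1,23,17.595
ID016-1,sample,ID016,1,24,18.388
ID016-1,sample,ID016,1,25,18.471
ID016-1,sample,ID016,1,26,18.905
ID016-1,sample,ID016,1,27,18.934
ID016-1,sample,ID016,1,28,19.211
ID016-2,sample,ID016,2,0,0
ID016-2,sample,ID016,2,1,1.684
ID016-2,sample,ID016,2,2,3.299
ID016-2,sample,ID016,2,3,4.215
ID016-2,sample,ID016,2,4,5.558
ID016-2,sample,ID016,2,5,7.088
ID016-2,sample,ID016,2,6,7.819
ID016-2,sample,ID016,2,7,9.057
ID016-2,sample,ID016,2,8,10.622
ID016-2,sample,ID016,2,9,11.564
ID016-2,sample,ID016,2,10,11.666
ID016-2,sample,ID016,2,11,12.935
ID016-2,sample,ID016,2,12,13.556
ID016-2,sample,ID016,2,13,14.233
ID016-2,sample,ID016,2,14,14.518
ID016-2,sample,ID016,2,15,15.134
ID016-2,sample,ID016,2,16,15.857
ID016-2,sample,ID016,2,17,15.366
ID016-2,sample,ID016,2,18,16.316
ID016-2,sample,ID016,2,19,16.887
ID016-2,sample,ID016,2,20,17.384
ID016-2,sample,ID016,2,21,17.406
ID016-2,sample,ID016,2,22,17.353
ID016-2,sample,ID016,2,23,18.089
ID016-2,sample,ID016,2,24,18.482
ID016-2,sample,ID016,2,25,18.645
ID016-2,sample,ID016,2,26,18.6
ID016-2,sample,ID016,2,27,18.804
ID016-2,sample,ID016,2,28,19.434
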