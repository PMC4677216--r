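"curve_id","cycle","fluorescence"
"target_sample",1,0.050166
"target_sample",2,0.049663
"target_sample",3,0.050244
"target_sample",4,0.050255
"target_sample",5,0.050748
"target_sample",6,0.049018
"target_sample",7,0.049113
"target_sample",8,0.049622
"target_sample",9,0.050823
"target_sample",10,0.04943
"target_sample",11,0.048806
"target_sample",12,0.050515
"target_sample",13,0.050774
"target_sample",14,0.050365
"target_sample",15,0.051232
"target_sample",16,0.052499
"target_sample",17,0.059201
"target_sample",18,0.068777
"target_sample",19,0.09517
"target_sample",20,0.152769
"target_sample",21,0.270113
"target_sample",22,0.461614
"target_sample",23,0.681872
"target_sample",24,0.859298
"target_sample",25,0.962246
"target_sample",26,1.012387
"target_sample",27,1.034768
"target_sample",28,1.043435
"target_sample",29,1.047459
"target_sample",30,1.049067
"target_sample",31,1.049433
"target_sample",32,1.049825
"target_sample",33,1.049537
"target_sample",34,1.050328
"target_sample",35,1.050397
"target_sample",36,1.049741
"target_sample",37,1.050246
"target_sample",38,1.049776
"target_sample",39,1.049655
"target_sample",40,1.050459
"target_calibrator",1,0.039031
"target_calibrator",2,0.040446
"target_calibrator",3,0.040605
"target_calibrator",4,0.040631
"target_calibrator",5,0.040698
"target_calibrator",6,0.040018
"target_calibrator",7,0.038844
"target_calibrator",8,0.04035
"target_calibrator",9,0.040038
"target_calibrator",10,0.040125
"target_calibrator",11,0.03966
"target_calibrator",12,0.04034
"target_calibrator",13,0.039545
"target_calibrator",14,0.040117
"target_calibrator",15,0.0409
"target_calibrator",16,0.04037
"target_calibrator",17,0.041157
"target_calibrator",18,0.040819
"target_calibrator",19,0.043968
"target_calibrator",20,0.049569
"target_calibrator",21,0.06224
"target_calibrator",22,0.094851
"target_calibrator",23,0.16425
"target_calibrator",24,0.297814
"target_calibrator",25,0.493487
"target_calibrator",26,0.697448
"target_calibrator",27,0.844207
"target_calibrator",28,0.924866
"target_calibrator",29,0.962472
"target_calibrator",30,0.979287
"target_calibrator",31,0.985573
"target_calibrator",32,0.987314
"target_calibrator",33,0.989907
"target_calibrator",34,0.989828
"target_calibrator",35,0.989185
"target_calibrator",36,0.989625
"target_calibrator",37,0.989787
"target_calibrator",38,0.990075
"target_calibrator",39,0.989637
"target_calibrator",40,0.989863
"reference_sample",1,0.060675
"reference_sample",2,0.060448
"reference_sample",3,0.060012
"reference_sample",4,0.059334
"reference_sample",5,0.060277
"reference_sample",6,0.06024
"reference_sample",7,0.060339
"reference_sample",8,0.059383
"reference_sample",9,0.061265
"reference_sample",10,0.060418
"reference_sample",11,0.06147
"reference_sample",12,0.062479
"reference_sample",13,0.066327
"reference_sample",14,0.076029
"reference_sample",15,0.098256
"reference_sample",16,0.148757
"reference_sample",17,0.255886
"reference_sample",18,0.442419
"reference_sample",19,0.684624
"reference_sample",20,0.899546
"reference_sample",21,1.036222
"reference_sample",22,1.106578
"reference_sample",23,1.137333
"reference_sample",24,1.151116
"reference_sample",25,1.156222
"reference_sample",26,1.15778
"reference_sample",27,1.158885
"reference_sample",28,1.159432
"reference_sample",29,1.159664
"reference_sample",30,1.160333
"reference_sample",31,1.160501
"reference_sample",32,1.160764
"reference_sample",33,1.160244
"reference_sample",34,1.16075
"reference_sample",35,1.159456
"reference_sample",36,1.160012
"reference_sample",37,1.16053
"reference_sample",38,1.160207
"reference_sample",39,1.160064
"reference_sample",40,1.160381
"reference_calibrator",1,0.051009
"reference_calibrator",2,0.050027
"reference_calibrator",3,0.050681
"reference_calibrator",4,0.050059
"reference_calibrator",5,0.050632
"reference_calibrator",6,0.050424
"reference_calibrator",7,0.049325
"reference_calibrator",8,0.050333
"reference_calibrator",9,0.050565
"reference_calibrator",10,0.050025
"reference_calibrator",11,0.051527
"reference_calibrator",12,0.052558
"reference_calibrator",13,0.055145
"reference_calibrator",14,0.062954
"reference_calibrator",15,0.081429
"reference_calibrator",16,0.121741
"reference_calibrator",17,0.210482
"reference_calibrator",18,0.37384
"reference_calibrator",19,0.599163
"reference_calibrator",20,0.816241
"reference_calibrator",21,0.962211
"reference_calibrator",22,1.039887
"reference_calibrator",23,1.073546
"reference_calibrator",24,1.089285
"reference_calibrator",25,1.096221
"reference_calibrator",26,1.09833
"reference_calibrator",27,1.098978
"reference_calibrator",28,1.099885
"reference_calibrator",29,1.099879
"reference_calibrator",30,1.099929
"reference_calibrator",31,1.099113
"reference_calibrator",32,1.100422
"reference_calibrator",33,1.09908
"reference_calibrator",34,1.099413
"reference_calibrator",35,1.098553
"reference_calibrator",36,1.10037
"reference_calibrator",37,1.099713
"reference_calibrator",38,1.100114
"reference_calibrator",39,1.100591
"reference_calibrator",40,1.100428
"no_template_control",1,0.049757
"no_template_control",2,0.049994
"no_template_control",3,0.050057
"no_template_control",4,0.049495
"no_template_control",5,0.049942
"no_template_control",6,0.050366
"no_template_control",7,0.050927
"no_template_control",8,0.05079
"no_template_control",9,0.049194
"no_template_control",10,0.050568
"no_template_control",11,0.050668
"no_template_control",12,0.050155
"no_template_control",13,0.049617
"no_template_control",14,0.049117
"no_template_control",15,0.049855
"no_template_control",16,0.049968
"no_template_control",17,0.049927
"no_template_control",18,0.049637
"no_template_control",19,0.049782
"no_template_control",20,0.049733
"no_template_control",21,0.050502
"no_template_control",22,0.050183
"no_template_control",23,0.050247
"no_template_control",24,0.049747
"no_template_control",25,0.04964
"no_template_control",26,0.049712
"no_template_control",27,0.050335
"no_template_control",28,0.051
"no_template_control",29,0.05256
"no_template_control",30,0.053644
"no_template_control",31,0.057098
"no_template_control",32,0.058152
"no_template_control",33,0.059249
"no_template_control",34,0.059824
"no_template_control",35,0.059215
"no_template_control",36,0.059518
"no_template_control",37,0.060118
"no_template_control",38,0.060656
"no_template_control",39,0.05972
"no_template_control",40,0.060138
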