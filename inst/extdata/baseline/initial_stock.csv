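specialty_id,sex,age,count
1,female,30,1.237612713367927e-06
2,female,30,24.563518403550422
3,female,30,18.155101069759557
1,male,30,2.7187241551920206e-06
2,male,30,26.127302961691882
3,male,30,8.08579347532533
1,female,31,8.0379704875740591e-05
2,female,31,23.477729556335866
3,female,31,46.028302539694515
1,male,31,0.00017657401453011366
2,male,31,24.97238965906417
3,male,31,20.49976736156453
1,female,32,0.00085506440119575728
2,female,32,23.08970454721084
3,female,32,64.68859558102038
1,male,32,0.0018783616366137036
2,male,32,24.559661856655481
3,male,32,28.810559746660825
1,female,33,0.0043153956619744003
2,female,33,22.844261392927695
3,female,33,76.322792223391914
1,male,33,0.0094798399359467232
2,male,33,24.298593081959829
3,male,33,33.992117863031339
1,female,34,0.014631164787101502
2,female,34,22.665773431206727
3,female,34,82.481244735518686
1,male,34,0.032140992651117202
2,male,34,24.108742060852666
3,male,34,36.734926892257796
1,female,35,0.038815421860586778
2,female,35,22.526474561834657
3,female,35,84.412026526123697
1,male,35,0.085267728641191934
2,male,35,23.960575022950675
3,male,35,37.594845145797862
1,female,36,0.087223519147007766
2,female,36,22.41298960639153
3,female,36,83.145252189313766
1,male,36,0.19160815483262242
2,male,36,23.839865287327942
3,male,36,37.030657944199262
1,female,37,0.17387567268660123
2,female,37,22.317841186965616
3,female,37,79.534999197485476
1,male,37,0.38196116299331384
2,male,37,23.738659444588912
3,male,37,35.422748411036558
1,female,38,0.31659393680262676
2,female,38,22.236428086433204
3,female,38,74.286790400899889
1,male,38,0.69547732830759335
2,male,38,23.652063350832506
3,male,38,33.085337438686686
1,female,39,0.53694586884834716
2,female,39,22.165722011289212
3,female,39,67.978442319635747
1,male,39,1.1795351549807367
2,male,39,23.576855922638824
3,male,39,30.275768956551982
1,female,40,0.85998786073796418
2,female,40,22.103628697235706
3,female,40,61.077196449198418
1,male,40,1.8891772401057543
2,male,40,23.51080956879332
3,male,40,27.202139753586764
1,female,41,1.3138014152490052
2,female,41,22.048644403671574
3,female,41,53.954439309820394
1,male,41,2.8860915892200123
2,male,41,23.45232481622314
3,male,41,24.029855392149578
1,female,42,1.9288156698148218
2,female,42,21.999657858821049
3,female,42,46.898675216240932
1,male,42,4.2371233713074181
2,male,42,23.400219646380243
3,male,42,20.887407930574796
1,female,43,2.7369092685950367
2,female,43,21.955829675861938
3,female,43,40.127124137240884
1,male,43,6.0123019574106165
2,male,43,23.353601234651912
3,male,43,17.871541297719087
1,female,44,3.7702842666744445
2,female,44,21.916515713792418
3,female,44,33.796170781614407
1,male,44,8.2823671711110958
2,male,44,23.311784432158898
3,male,44,15.051905034675604
1,female,45,5.0601041032377436
2,female,45,21.881216709644988
3,female,45,28.010811863330808
1,male,45,11.1157772578318
2,male,45,23.274238191410557
3,male,45,12.475261852457711
1,female,46,6.6348867640828431
2,female,46,21.849544355210224
3,female,46,22.833202908895601
1,male,46,14.575179066630387
2,male,46,23.240549483374842
3,male,46,10.169294150008966
1,female,47,8.5186430005811129
2,female,47,21.821198120866825
3,female,47,18.29037838718466
1,male,47,18.713318185066321
2,male,47,23.210398645846372
3,male,47,8.1460423522879246
1,female,48,10.72874777791937
2,female,48,21.795949424571734
3,female,48,14.381201572966907
1,male,48,23.56836304583166
2,male,48,23.183542544588729
3,male,48,6.4050001924651481
1,female,49,13.273530832509072
2,female,49,21.773631091483512
3,female,49,11.082589268783728
1,male,49,29.158611986801901
2,male,49,23.159803361927029
3,male,49,4.9358870355453659
1,female,50,16.149569087847553
2,female,50,21.754130893652889
3,female,50,8.3550490059486151
1,male,50,35.476545369020236
2,male,50,23.139061725156463
3,male,50,3.7211139986904747
1,female,51,19.338659342308372
2,female,51,21.737388540161046
3,female,51,6.1475612902443322
1,male,51,42.482175332448492
2,male,51,23.121253505064104
3,male,51,2.7379583720752327
1,female,52,22.80444352347374
2,female,52,21.723395952095945
3,female,52,4.4018360513832748
1,male,52,50.095632327710859
2,male,52,23.106370108411031
3,male,52,1.9604593269387995
1,female,53,26.488649968352544
2,female,53,21.712201113906605
3,female,53,3.0559702053443019
1,male,53,58.188908153189864
2,male,53,23.094462574474946
3,male,53,1.3610468954271053
1,female,54,30.306901080564071
2,female,54,21.703916358642214
3,female,54,2.0475318386468508
1,male,54,66.57664643127282
2,male,54,23.085650387751524
3,male,54,0.91191558327528754
1,female,55,34.144017640716847
2,female,55,21.698732788224962
3,female,55,1.3160957836146014
1,male,55,75.005827358144359
2,male,55,23.080136816263526
3,male,55,0.58615364679955806
1,female,56,37.848718139448323
2,female,56,21.696943957985575
3,female,56,0.80525516237024541
1,male,56,83.144123470378062
2,male,56,23.078234103922252
3,male,56,0.35863898046322479
1,female,57,41.227558525281005
2,female,57,21.698984598619258
3,female,57,0.46413378102259845
1,male,57,90.566586793741408
2,male,57,23.080404657635132
3,male,57,0.20671269655015501
1,female,58,44.037865100187574
2,female,58,21.705495430693887
3,female,58,0.2484250495376876
1,male,58,96.740124190510244
2,male,58,23.087329988092758
3,male,58,0.11064183211874619
1,female,59,45.979240697963036
2,female,59,21.717436543333811
3,female,59,0.12098443258611924
1,male,59,101.0048385676026
2,male,59,23.100031306467319
3,male,59,0.053883210666903554
1,female,60,46.682876706702764
2,female,60,21.736298871058469
3,female,60,0.052004411059353432
1,male,60,102.55055007554095
2,male,60,23.120094464477845
3,male,60,0.023161365283295855
1,female,61,45.697130237683488
2,female,61,21.764535397614011
3,female,61,0.018803757681325573
1,male,61,100.38511277252158
2,male,61,23.150128609903685
3,male,61,0.0083746876752184615
1,female,62,42.465860563942165
2,female,62,21.806558479927137
3,female,62,0.0052669760101080199
1,male,62,93.286825223395255
2,male,62,23.19482700306305
3,male,62,0.0023457693842400896
1,female,63,36.289975893363433
2,female,63,21.871531476677891
3,female,63,0.0009757286883307311
1,male,63,79.719958422317987
2,male,63,23.263936368527183
3,male,63,0.00043456330160198086
1,female,64,26.237290746268652
2,female,64,21.984298356799517
3,female,64,8.347616902643556e-05
1,male,64,57.636735101532963
2,male,64,23.383882314078562
3,male,64,3.7178039398711333e-05
1,female,65,10.732069991902597
2,female,65,22.322972961651384
3,female,65,1.1017247577492907e-06
1,male,65,23.575661115177066
2,male,65,23.7441179228795
3,male,65,4.906785604543911e-07
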