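K	run	lnP
1	1	-9616.81710961573
1	2	-9572.31281313043
1	3	-9625.10983725255
1	4	-9598.59714467145
1	5	-9565.77118254595
1	6	-9612.05815962909
1	7	-9609.44332770334
1	8	-9612.70742625048
1	9	-9605.71547269732
1	10	-9597.23783550392
2	1	-9175.44739312293
2	2	-9216.03558909306
2	3	-9221.60785200055
2	4	-9203.15068712214
2	5	-9221.43520079756
2	6	-9202.779722811
2	7	-9211.94626189426
2	8	-9243.67933520183
2	9	-9195.18365488127
2	10	-9205.18710813469
3	1	-8781.98976109333
3	2	-8781.16261212265
3	3	-8770.64076193161
3	4	-8785.86477820884
3	5	-8783.61982139476
3	6	-8805.86963697405
3	7	-8771.62821855028
3	8	-8770.02452345187
3	9	-8813.14164188971
3	10	-8817.05590880004
4	1	-8783.68169923277
4	2	-8767.80611664682
4	3	-8745.69078856644
4	4	-8765.65792722085
4	5	-8760.41556426723
4	6	-8770.96852335164
4	7	-8810.19065291925
4	8	-8830.00945477276
4	9	-8825.24371744904
4	10	-8792.8521625191
5	1	-8748.99879261034
5	2	-8796.0484636343
5	3	-8781.49157839765
5	4	-8742.08664090555
5	5	-8789.13137881841
5	6	-8768.75553274714
5	7	-8797.74017023023
5	8	-8789.2048915239
5	9	-8794.48656972135
5	10	-8781.38422311668
6	1	-8740.73502874103
6	2	-8766.24547805134
6	3	-8749.55954277338
6	4	-8781.83669665902
6	5	-8772.24401310072
6	6	-8788.49906171731
6	7	-8754.93390403409
6	8	-8772.25218140406
6	9	-8771.2818185644
6	10	-8765.33449412909
7	1	-8782.73165606297
7	2	-8742.90339153743
7	3	-8771.56740837924
7	4	-8750.0727692194
7	5	-8775.20115861224
7	6	-8766.82772540799
7	7	-8802.04658240956
7	8	-8766.03404562738
7	9	-8785.44766884362
7	10	-8765.59332219618
8	1	-8754.08194641639
8	2	-8754.51228371035
8	3	-8743.05943095956
8	4	-8749.35264314804
8	5	-8741.72937420656
8	6	-8753.10696953251
8	7	-8730.53029215034
8	8	-8747.57819714453
8	9	-8746.21652617045
8	10	-8761.25770139652
9	1	-8730.03167669997
9	2	-8774.84604986726
9	3	-8720.48941805593
9	4	-8740.48165745473
9	5	-8726.48631049372
9	6	-8754.20619210107
9	7	-8692.25534707245
9	8	-8749.46864024393
9	9	-8741.51545113333
9	10	-8750.43680112957
10	1	-8711.47905730875
10	2	-8751.24822343229
10	3	-8718.85932267404
10	4	-8711.98538830176
10	5	-8710.20108632624
10	6	-8722.32783824841
10	7	-8736.93167627397
10	8	-8740.80378500009
10	9	-8733.65111186533
10	10	-8731.18599299988
11	1	-8759.90773935648
11	2	-8697.29377437658
11	3	-8706.48410868492
11	4	-8715.83033473786
11	5	-8721.1569128417
11	6	-8702.12377171795
11	7	-8724.57730761551
11	8	-8759.31305299281
11	9	-8735.07020891647
11	10	-8694.3969675112
12	1	-8729.05809919484
12	2	-8677.55241213981
12	3	-8657.99715959755
12	4	-8707.20702989756
12	5	-8737.01439346255
12	6	-8694.02137964104
12	7	-8741.09991680891
12	8	-8700.72559886412
12	9	-8708.95140870854
12	10	-8714.04063601441
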