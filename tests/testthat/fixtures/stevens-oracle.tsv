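twoS	k	q	row	col	value
2	2	0	1	1	1
2	2	0	2	2	-2
2	2	0	3	3	1
2	2	2	1	3	1
2	2	2	3	1	1
3	2	0	1	1	3
3	2	0	2	2	-3
3	2	0	3	3	-3
3	2	0	4	4	3
3	2	2	1	3	1.7320508075688772
3	2	2	2	4	1.7320508075688772
3	2	2	3	1	1.7320508075688772
3	2	2	4	2	1.7320508075688772
4	2	0	1	1	6
4	2	0	2	2	-3
4	2	0	3	3	-6
4	2	0	4	4	-3
4	2	0	5	5	6
4	2	2	1	3	2.4494897427831779
4	2	2	2	4	3
4	2	2	3	1	2.4494897427831779
4	2	2	3	5	2.4494897427831779
4	2	2	4	2	3
4	2	2	5	3	2.4494897427831779
4	4	0	1	1	12
4	4	0	2	2	-48
4	4	0	3	3	72
4	4	0	4	4	-48
4	4	0	5	5	12
4	4	2	1	3	7.3484692283495345
4	4	2	2	4	-12
4	4	2	3	1	7.3484692283495345
4	4	2	3	5	7.3484692283495345
4	4	2	4	2	-12
4	4	2	5	3	7.3484692283495345
4	4	4	1	5	12
4	4	4	5	1	12
5	2	0	1	1	10
5	2	0	2	2	-2
5	2	0	3	3	-8
5	2	0	4	4	-8
5	2	0	5	5	-2
5	2	0	6	6	10
5	2	2	1	3	3.1622776601683795
5	2	2	2	4	4.2426406871192848
5	2	2	3	1	3.1622776601683795
5	2	2	3	5	4.2426406871192848
5	2	2	4	2	4.2426406871192848
5	2	2	4	6	3.1622776601683795
5	2	2	5	3	4.2426406871192848
5	2	2	6	4	3.1622776601683795
5	4	0	1	1	60
5	4	0	2	2	-180
5	4	0	3	3	120
5	4	0	4	4	120
5	4	0	5	5	-180
5	4	0	6	6	60
5	4	2	1	3	28.460498941515414
5	4	2	2	4	-21.213203435596427
5	4	2	3	1	28.460498941515414
5	4	2	3	5	-21.213203435596427
5	4	2	4	2	-21.213203435596427
5	4	2	4	6	28.460498941515414
5	4	2	5	3	-21.213203435596427
5	4	2	6	4	28.460498941515414
5	4	4	1	5	26.832815729997478
5	4	4	2	6	26.832815729997478
5	4	4	5	1	26.832815729997478
5	4	4	6	2	26.832815729997478
6	2	0	1	1	15
6	2	0	3	3	-9
6	2	0	4	4	-12
6	2	0	5	5	-9
6	2	0	7	7	15
6	2	2	1	3	3.872983346207417
6	2	2	2	4	5.4772255750516612
6	2	2	3	1	3.872983346207417
6	2	2	3	5	6
6	2	2	4	2	5.4772255750516612
6	2	2	4	6	5.4772255750516612
6	2	2	5	3	6
6	2	2	5	7	3.872983346207417
6	2	2	6	4	5.4772255750516612
6	2	2	7	5	3.872983346207417
6	4	0	1	1	180
6	4	0	2	2	-420
6	4	0	3	3	60
6	4	0	4	4	360
6	4	0	5	5	60
6	4	0	6	6	-420
6	4	0	7	7	180
6	4	2	1	3	69.713700231733498
6	4	2	2	4	-16.431676725154983
6	4	2	3	1	69.713700231733498
6	4	2	3	5	-60
6	4	2	4	2	-16.431676725154983
6	4	2	4	6	-16.431676725154983
6	4	2	5	3	-60
6	4	2	5	7	69.713700231733498
6	4	2	6	4	-16.431676725154983
6	4	2	7	5	69.713700231733498
6	4	4	1	5	46.475800154489001
6	4	4	2	6	60
6	4	4	3	7	46.475800154489001
6	4	4	5	1	46.475800154489001
6	4	4	6	2	60
6	4	4	7	3	46.475800154489001
6	6	0	1	1	180
6	6	0	2	2	-1080
6	6	0	3	3	2700
6	6	0	4	4	-3600
6	6	0	5	5	2700
6	6	0	6	6	-1080
6	6	0	7	7	180
6	6	2	1	3	92.951600308978001
6	6	2	2	4	-262.90682760247972
6	6	2	3	1	92.951600308978001
6	6	2	3	5	360
6	6	2	4	2	-262.90682760247972
6	6	2	4	6	-262.90682760247972
6	6	2	5	3	360
6	6	2	5	7	92.951600308978001
6	6	2	6	4	-262.90682760247972
6	6	2	7	5	92.951600308978001
6	6	4	1	5	232.37900077244501
6	6	4	2	6	-360
6	6	4	3	7	232.37900077244501
6	6	4	5	1	232.37900077244501
6	6	4	6	2	-360
6	6	4	7	3	232.37900077244501
6	6	6	1	7	360
6	6	6	7	1	360
7	2	0	1	1	21
7	2	0	2	2	3
7	2	0	3	3	-9
7	2	0	4	4	-15
7	2	0	5	5	-15
7	2	0	6	6	-9
7	2	0	7	7	3
7	2	0	8	8	21
7	2	2	1	3	4.5825756949558398
7	2	2	2	4	6.7082039324993694
7	2	2	3	1	4.5825756949558398
7	2	2	3	5	7.745966692414834
7	2	2	4	2	6.7082039324993694
7	2	2	4	6	7.745966692414834
7	2	2	5	3	7.745966692414834
7	2	2	5	7	6.7082039324993694
7	2	2	6	4	7.745966692414834
7	2	2	6	8	4.5825756949558398
7	2	2	7	5	6.7082039324993694
7	2	2	8	6	4.5825756949558398
7	4	0	1	1	420
7	4	0	2	2	-780
7	4	0	3	3	-180
7	4	0	4	4	540
7	4	0	5	5	540
7	4	0	6	6	-180
7	4	0	7	7	-780
7	4	0	8	8	420
7	4	2	1	3	137.4772708486752
7	4	2	2	4	13.416407864998739
7	4	2	3	1	137.4772708486752
7	4	2	3	5	-92.951600308978001
7	4	2	4	2	13.416407864998739
7	4	2	4	6	-92.951600308978001
7	4	2	5	3	-92.951600308978001
7	4	2	5	7	13.416407864998739
7	4	2	6	4	-92.951600308978001
7	4	2	6	8	137.4772708486752
7	4	2	7	5	13.416407864998739
7	4	2	8	6	137.4772708486752
7	4	4	1	5	70.992957397195397
7	4	4	2	6	103.92304845413264
7	4	4	3	7	103.92304845413264
7	4	4	4	8	70.992957397195397
7	4	4	5	1	70.992957397195397
7	4	4	6	2	103.92304845413264
7	4	4	7	3	103.92304845413264
7	4	4	8	4	70.992957397195397
7	6	0	1	1	1260
7	6	0	2	2	-6300
7	6	0	3	3	11340
7	6	0	4	4	-6300
7	6	0	5	5	-6300
7	6	0	6	6	11340
7	6	0	7	7	-6300
7	6	0	8	8	1260
7	6	2	1	3	549.90908339470082
7	6	2	2	4	-1126.978260659894
7	6	2	3	1	549.90908339470082
7	6	2	3	5	650.66120216284605
7	6	2	4	2	-1126.978260659894
7	6	2	4	6	650.66120216284605
7	6	2	5	3	650.66120216284605
7	6	2	5	7	-1126.978260659894
7	6	2	6	4	650.66120216284605
7	6	2	6	8	549.90908339470082
7	6	2	7	5	-1126.978260659894
7	6	2	8	6	549.90908339470082
7	6	4	1	5	1064.894360957931
7	6	4	2	6	-727.46133917892848
7	6	4	3	7	-727.46133917892848
7	6	4	4	8	1064.894360957931
7	6	4	5	1	1064.894360957931
7	6	4	6	2	-727.46133917892848
7	6	4	7	3	-727.46133917892848
7	6	4	8	4	1064.894360957931
7	6	6	1	7	952.47047198325265
7	6	6	2	8	952.47047198325265
7	6	6	7	1	952.47047198325265
7	6	6	8	2	952.47047198325265
8	2	0	1	1	28
8	2	0	2	2	7
8	2	0	3	3	-8
8	2	0	4	4	-17
8	2	0	5	5	-20
8	2	0	6	6	-17
8	2	0	7	7	-8
8	2	0	8	8	7
8	2	0	9	9	28
8	2	2	1	3	5.2915026221291814
8	2	2	2	4	7.9372539331937721
8	2	2	3	1	5.2915026221291814
8	2	2	3	5	9.4868329805051381
8	2	2	4	2	7.9372539331937721
8	2	2	4	6	10
8	2	2	5	3	9.4868329805051381
8	2	2	5	7	9.4868329805051381
8	2	2	6	4	10
8	2	2	6	8	7.9372539331937721
8	2	2	7	5	9.4868329805051381
8	2	2	7	9	5.2915026221291814
8	2	2	8	6	7.9372539331937721
8	2	2	9	7	5.2915026221291814
8	4	0	1	1	840
8	4	0	2	2	-1260
8	4	0	3	3	-660
8	4	0	4	4	540
8	4	0	5	5	1080
8	4	0	6	6	540
8	4	0	7	7	-660
8	4	0	8	8	-1260
8	4	0	9	9	840
8	4	2	1	3	238.11761799581316
8	4	2	2	4	79.372539331937716
8	4	2	3	1	238.11761799581316
8	4	2	3	5	-104.35516278555652
8	4	2	4	2	79.372539331937716
8	4	2	4	6	-180
8	4	2	5	3	-104.35516278555652
8	4	2	5	7	-104.35516278555652
8	4	2	6	4	-180
8	4	2	6	8	79.372539331937716
8	4	2	7	5	-104.35516278555652
8	4	2	7	9	238.11761799581316
8	4	2	8	6	79.372539331937716
8	4	2	9	7	238.11761799581316
8	4	4	1	5	100.39920318408906
8	4	4	2	6	158.74507866387543
8	4	4	3	7	180
8	4	4	4	8	158.74507866387543
8	4	4	5	1	100.39920318408906
8	4	4	5	9	100.39920318408906
8	4	4	6	2	158.74507866387543
8	4	4	7	3	180
8	4	4	8	4	158.74507866387543
8	4	4	9	5	100.39920318408906
8	6	0	1	1	5040
8	6	0	2	2	-21420
8	6	0	3	3	27720
8	6	0	4	4	1260
8	6	0	5	5	-25200
8	6	0	6	6	1260
8	6	0	7	7	27720
8	6	0	8	8	-21420
8	6	0	9	9	5040
8	6	2	1	3	1904.9409439665053
8	6	2	2	4	-2857.4114159497576
8	6	2	3	1	1904.9409439665053
8	6	2	4	2	-2857.4114159497576
8	6	2	4	6	2520
8	6	2	6	4	2520
8	6	2	6	8	-2857.4114159497576
8	6	2	7	9	1904.9409439665053
8	6	2	8	6	-2857.4114159497576
8	6	2	9	7	1904.9409439665053
8	6	4	1	5	3011.976095522672
8	6	4	2	6	-476.23523599162633
8	6	4	3	7	-2520
8	6	4	4	8	-476.23523599162633
8	6	4	5	1	3011.976095522672
8	6	4	5	9	3011.976095522672
8	6	4	6	2	-476.23523599162633
8	6	4	7	3	-2520
8	6	4	8	4	-476.23523599162633
8	6	4	9	5	3011.976095522672
8	6	6	1	7	1904.9409439665053
8	6	6	2	8	2520
8	6	6	3	9	1904.9409439665053
8	6	6	7	1	1904.9409439665053
8	6	6	8	2	2520
8	6	6	9	3	1904.9409439665053
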