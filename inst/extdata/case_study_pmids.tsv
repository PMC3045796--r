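case	name	pmid
FADS1	FADS1	10860662
FADS1	FADS1	15168598
FADS1	FADS1	16367923
FADS1	FADS1	16670158
FADS1	FADS1	16893529
FADS1	FADS1	17786358
FADS1	FADS1	17823443
FADS1	FADS1	18030445
FADS1	FADS1	18155511
FADS1	FADS1	18320251
FADS1	FADS1	18479586
FADS1	FADS1	18626191
FADS1	FADS1	18652865
FADS1	FADS1	18671863
FADS1	FADS1	18763007
FADS1	FADS1	18842780
FADS1	FADS1	18936223
FADS1	FADS1	19043545
FADS1	FADS1	19060906
FADS1	FADS1	19060910
FADS1	FADS1	19091074
FADS1	FADS1	19148276
FADS1	FADS1	19195843
FADS1	FADS1	19443042
FADS1	FADS1	19573581
FADS1	FADS1	19689798
FADS1	FADS1	19752397
FADS1	FADS1	19776639
FADS1	D5D	2585642
FADS1	D5D	3821914
FADS1	D5D	3891589
FADS1	D5D	3904980
FADS1	D5D	4023915
FADS1	D5D	9976912
FADS1	D5D	11414679
FADS1	D5D	11686594
FADS1	D5D	11792729
FADS1	D5D	12440976
FADS1	D5D	15740094
FADS1	D5D	15782269
FADS1	D5D	16132958
FADS1	D5D	16734456
FADS1	D5D	16988497
FADS1	D5D	17307914
FADS1	D5D	17639524
FADS1	D5D	17852835
FADS1	D5D	18030445
FADS1	D5D	19060426
FADS1	D5D	19228394
FADS1	D5D	19340699
FADS1	D5D	19712485
FADS1	fatty acid desaturase 1	10860662
FADS1	fatty acid desaturase 1	15168598
FADS1	fatty acid desaturase 1	16893529
FADS1	fatty acid desaturase 1	17176482
FADS1	fatty acid desaturase 1	17761144
FADS1	fatty acid desaturase 1	18222430
FADS1	fatty acid desaturase 1	18479586
FADS1	fatty acid desaturase 1	19573581
FADS1	TU12	1717594
FADS1	TU12	3835499
FADS1	TU12	6699682
ADD2	ADD2	7490111
ADD2	ADD2	9012501
ADD2	ADD2	9244430
ADD2	ADD2	10485892
ADD2	ADD2	11082136
ADD2	ADD2	12951058
ADD2	ADD2	15474463
ADD2	ADD2	15528469
ADD2	ADD2	15699449
ADD2	ADD2	15716695
ADD2	ADD2	15928065
ADD2	ADD2	15963851
ADD2	ADD2	16497648
ADD2	ADD2	16565244
ADD2	ADD2	16604465
ADD2	ADD2	17301826
ADD2	ADD2	17465710
ADD2	ADD2	17854487
ADD2	ADD2	18003638
ADD2	ADD2	18482449
ADD2	ADD2	18667944
ADD2	ADD2	18723693
ADD2	ADD2	18787518
ADD2	ADD2	18959617
ADD2	ADD2	19838659
ADD2	ADD2	19900187
ADD2	adducing 2 isoform a	1556101
ADD2	adducing 2 isoform a	2524283
ADD2	adducing 2 isoform a	7864813
ADD2	adducing 2 isoform a	8239658
ADD2	adducing 2 isoform a	8952067
ADD2	adducing 2 isoform a	8913030
ADD2	adducing 2 isoform a	9244430
ADD2	adducing 2 isoform a	9354614
ADD2	adducing 2 isoform a	9524222
ADD2	adducing 2 isoform a	11598638
ADD2	adducing 2 isoform a	12675919
ADD2	adducing 2 isoform a	12969891
ADD2	adducing 2 isoform a	15329129
ADD2	adducing 2 isoform a	17610345
ADD2	adducing 2 isoform a	18344231
ADD2	adducing 2 isoform a	18757509
ADD2	ADDB	1646786
ADD2	ADDB	1905712
ADD2	ADDB	2177138
ADD2	ADDB	7565602
ADD2	ADDB	7746142
ADD2	ADDB	8387145
ADD2	ADDB	8510642
ADD2	ADDB	8752329
ADD2	ADDB	8885269
ADD2	ADDB	9004227
ADD2	ADDB	9023205
ADD2	ADDB	9781875
ADD2	ADDB	11292820
ADD2	ADDB	11544244
ADD2	ADDB	11810266
ADD2	ADDB	15066813
ADD2	ADDB	15099822
ADD2	ADDB	16385024
ADD2	ADDB	16780573
ADD2	ADDB	17499012
ADD2	ADDB	18573180
ADD2	ADDB	19129187
ADD2	ADDB	19395381
ADD2	ADDB	19542287
ADD2	ADDB	19620647
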