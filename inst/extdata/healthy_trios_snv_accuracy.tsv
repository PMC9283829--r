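family	depth_label	category	engine	accuracy	n_true	n_total
JK-7	100X	AAAB	bayes	96.8	631788	652391
JK-7	100X	ABAA	bayes	72.6	909990	1253908
JK-7	100X	ABAA	haplo	98.8	1171962	1186610
JK-7	100X	ABAA	combined	96.1	1209126	1253908
JK-7	100X	ABAB	bayes	61.4	429479	698962
JK-7	100X	ABAB	haplo	96.4	572296	593618
JK-7	100X	ABAB	combined	89.8	627424	698962
JK-16	100X	AAAB	bayes	97.7	576306	590073
JK-16	100X	ABAA	bayes	91.8	1014224	1104405
JK-16	100X	ABAA	haplo	99.2	1061980	1070070
JK-16	100X	ABAA	combined	98.0	1082868	1104405
JK-16	100X	ABAB	bayes	85.9	540677	629324
JK-16	100X	ABAB	haplo	97.5	562304	576574
JK-16	100X	ABAB	combined	94.9	597082	629324
JK-18	100X	AAAB	bayes	96.4	463476	480708
JK-18	100X	ABAA	bayes	75.7	901292	1190790
JK-18	100X	ABAA	haplo	99.0	1112107	1123516
JK-18	100X	ABAA	combined	96.7	1151107	1190790
JK-18	100X	ABAB	bayes	65.9	439900	667062
JK-18	100X	ABAB	haplo	92.7	488305	526841
JK-18	100X	ABAB	combined	86.5	576938	667062
JK-28	100X	AAAB	bayes	95.2	313500	329369
JK-28	100X	ABAA	bayes	69.5	440760	633774
JK-28	100X	ABAA	haplo	98.5	581675	590448
JK-28	100X	ABAA	combined	96.0	608483	633774
JK-28	100X	ABAB	bayes	57.3	222910	388712
JK-28	100X	ABAB	haplo	93.1	268695	288587
JK-28	100X	ABAB	combined	83.2	323556	388712
JK-53	128X	AAAB	bayes	95.6	540046	564870
JK-53	128X	ABAA	bayes	59.6	667583	1120831
JK-53	128X	ABAA	haplo	97.3	926919	952660
JK-53	128X	ABAA	combined	92.0	998262	1085313
JK-53	128X	ABAB	bayes	49.4	325416	658784
JK-53	128X	ABAB	haplo	89.1	363047	407606
JK-53	128X	ABAB	combined	74.7	481240	644645
JK-53	256.12X	AAAB	bayes	95.0	590368	621392
JK-53	256.12X	ABAA	bayes	63.5	706502	1112899
JK-53	256.12X	ABAA	haplo	97.7	979699	1002260
JK-53	256.12X	ABAA	combined	93.6	1041875	1112899
JK-53	256.12X	ABAB	bayes	51.0	341350	668854
JK-53	256.12X	ABAB	haplo	93.9	462865	492889
JK-53	256.12X	ABAB	combined	81.8	547115	668854
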