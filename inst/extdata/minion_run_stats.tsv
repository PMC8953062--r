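sample	sample_type	region	pass_reads	filtered_reads	min_bp	avg_bp	max_bp	filtered_avg_bp
1	lavage	V1-9	115957	91449	128	1434.3	4377	1633.5
1	swab	V1-9	63547	31462	155	1078.0	4193	1619.3
2	lavage	V1-9	33721	28718	158	1507.2	4486	1607.0
2	swab	V1-9	53584	33294	145	1203.6	3746	1613.6
3	lavage	V1-9	28071	20958	154	1396.3	4875	1613.8
3	swab	V1-9	23053	20073	162	1521.0	3990	1614.5
4	lavage	V1-9	30603	25756	155	1502.9	4977	1639.5
4	swab	V1-9	37597	19588	161	1103.2	3383	1644.9
5	lavage	V1-9	15836	10688	147	1346.1	3393	1632.8
6	lavage	V1-9	38020	32255	144	1517.2	3787	1642.4
7	lavage	V1-9	61432	37018	158	1218.8	5035	1631.4
8	lavage	V1-9	52071	33906	111	1257.5	3344	1603.2
9	lavage	V1-9	119745	103212	125	1530.5	4664	1649.4
10	lavage	V1-9	102333	84028	150	1496.5	4980	1650.2
11	lavage	V1-9	61756	54116	121	1541.3	3519	1647.8
12	lavage	V1-9	101755	77756	120	1433.9	4759	1635.8
13	lavage	V1-9	71041	56601	134	1437.5	4828	1599.2
14	lavage	V1-9	42629	31447	159	1367.7	4981	1629.0
15	lavage	V1-9	52908	42910	172	1452.9	3333	1630.4
16	lavage	V1-9	52230	43549	153	1480.3	4345	1633.0
17	lavage	V1-9	38219	31757	154	1478.3	3453	1625.3
18	lavage	V1-9	28886	23816	185	1464.7	3328	1631.8
5	lavage	V3-4	74096	29505	147	589.5	3038	574.8
6	lavage	V3-4	83983	33677	141	586.1	2099	571.8
9	lavage	V3-4	49642	21614	148	588.2	2275	574.2
10	lavage	V3-4	65561	28440	139	587.2	2873	574.5
11	lavage	V3-4	98126	40485	124	587.4	2568	571.7
14	lavage	V3-4	79631	35009	127	584.9	1849	571.2
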