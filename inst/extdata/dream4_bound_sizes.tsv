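size	network	gold	lower	upper	non_inferable
10	1	15	5	21	16
10	2	16	2	47	45
10	3	15	1	59	58
10	4	13	3	40	37
10	5	12	5	33	28
100	1	176	93	639	546
100	2	249	60	667	607
100	3	195	35	2375	2340
100	4	211	38	2316	2278
100	5	193	60	953	893
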