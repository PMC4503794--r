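volume_index	kind	flip_deg	tr_ms	trf_ms	te_ms	pulse_shape
1	bssfp	5	3.66	0.8	1.83	rectangular
2	bssfp	10	3.66	0.8	1.83	rectangular
3	bssfp	15	3.66	0.8	1.83	rectangular
4	bssfp	20	3.66	0.8	1.83	rectangular
5	bssfp	25	3.66	0.8	1.83	rectangular
6	bssfp	30	3.66	0.8	1.83	rectangular
7	bssfp	35	3.66	0.8	1.83	rectangular
8	bssfp	40	3.66	0.8	1.83	rectangular
9	bssfp	40	3.66	0.23	1.83	rectangular
10	bssfp	40	3.73	0.3	1.865	rectangular
11	bssfp	40	3.83	0.4	1.915	rectangular
12	bssfp	40	3.95	0.52	1.975	rectangular
13	bssfp	40	4.09	0.66	2.045	rectangular
14	bssfp	40	4.27	0.84	2.135	rectangular
15	bssfp	40	4.47	1.04	2.235	rectangular
16	bssfp	40	4.73	1.3	2.365	rectangular
17	bssfp	40	5.03	1.6	2.515	rectangular
18	bssfp	40	5.33	1.9	2.665	rectangular
19	bssfp	40	5.63	2.2	2.815	rectangular
20	bssfp	40	5.78	2.35	2.89	rectangular
21	bssfp	40	5.88	2.45	2.94	rectangular
22	bssfp	40	5.96	2.53	2.98	rectangular
23	spgr	5	30	NA	5	rectangular
24	spgr	15	30	NA	5	rectangular
25	spgr	25	30	NA	5	rectangular
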