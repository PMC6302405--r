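# synthetic match quality-score profile
# trained with train_quality_profile() on this package's read simulator
# (1e5 pairs, default quality ramp, shared first-strand error rate 2e-4)
# NOT derived from real instrument data
0	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37	38	39	40
0	10	12	13	13	12	12	12	12	12	13	15	15	14	15	16	16	16	16	16	17	16	16	16	16	17	16	16	17	18	17	15	15	15	15	15	15	15	16	17	19	17
1	12	11	13	13	14	13	13	13	13	13	14	16	16	15	16	17	16	17	17	18	18	17	17	17	17	17	17	18	18	18	16	16	16	16	16	16	16	17	18	19	18
2	13	13	12	14	14	14	14	14	14	14	14	16	17	17	16	17	17	18	17	18	19	18	18	18	18	18	17	18	19	18	17	17	17	17	17	17	17	18	19	19	18
3	13	13	14	13	15	15	15	15	15	15	15	15	17	17	17	17	18	18	19	19	19	19	19	18	19	19	18	19	20	19	18	18	18	18	18	17	17	19	20	20	19
4	12	14	14	15	14	15	16	16	15	15	15	15	17	18	18	18	18	19	19	19	19	20	19	19	20	19	19	19	20	20	19	19	18	19	19	18	18	20	21	20	20
5	12	13	14	15	15	15	16	16	17	16	17	16	16	18	19	19	19	19	19	20	20	20	20	20	20	20	20	20	22	21	20	19	19	19	19	19	19	21	23	21	20
6	12	13	14	15	16	16	16	17	17	17	17	18	17	18	19	19	20	19	20	21	21	21	21	21	21	21	21	21	23	23	21	20	20	20	20	20	20	22	24	21	21
7	12	13	14	15	16	16	17	17	18	18	18	18	19	18	19	20	20	20	20	21	22	22	22	22	21	22	22	22	23	23	23	22	22	22	22	21	21	24	25	22	21
8	12	13	14	15	15	17	17	18	18	18	19	19	19	19	19	20	20	21	21	21	22	23	22	23	23	24	24	23	24	25	24	23	23	23	23	23	23	25	26	23	23
9	13	13	14	15	15	16	17	18	18	19	19	19	20	20	20	20	21	21	23	22	22	24	24	24	24	25	25	24	25	26	25	25	24	24	24	24	24	27	27	25	24
10	15	14	14	15	15	17	17	18	19	19	20	20	20	20	21	21	21	22	23	24	24	25	26	26	26	26	26	26	26	28	27	26	26	25	25	26	26	28	27	26	26
11	15	16	16	15	15	16	18	18	19	19	20	20	21	21	21	21	22	22	23	27	26	26	27	27	27	27	28	28	27	28	28	28	27	26	26	27	28	29	28	27	28
12	14	16	17	17	17	16	17	19	19	20	20	21	21	22	22	22	22	23	24	26	27	27	27	28	28	28	29	28	28	29	30	29	28	28	28	28	29	30	29	28	29
13	15	15	17	17	18	18	18	18	19	20	20	21	22	22	23	23	25	24	26	26	28	28	28	29	29	29	30	30	30	30	31	30	30	29	29	29	30	31	29	29	29
14	16	16	16	17	18	19	19	19	19	20	21	21	22	23	23	25	25	27	26	27	28	30	29	29	30	30	30	31	30	31	32	31	31	31	30	31	32	32	30	30	30
15	16	17	17	17	18	19	19	20	20	20	21	21	22	23	25	26	26	26	28	27	29	30	30	30	31	31	31	33	32	32	33	32	33	32	32	32	33	33	31	31	32
16	16	16	17	18	18	19	20	20	20	21	21	22	22	25	25	26	27	27	28	29	29	30	32	31	31	32	32	33	33	33	33	34	34	33	33	34	34	33	32	32	32
17	16	17	18	18	19	19	19	20	21	21	22	22	23	24	27	26	27	28	29	29	30	31	32	33	32	33	33	34	35	34	35	35	36	35	35	36	35	35	34	34	32
18	16	17	17	19	19	19	20	20	21	23	23	23	24	26	26	28	28	29	30	30	31	31	32	33	34	34	34	35	36	36	36	37	37	37	37	37	37	35	35	35	34
19	17	18	18	19	19	20	21	21	21	22	24	27	26	26	27	27	29	29	30	31	31	33	33	34	35	35	35	36	37	37	37	37	37	38	38	38	38	36	37	36	35
20	16	18	19	19	19	20	21	22	22	22	24	26	27	28	28	29	29	30	31	31	32	33	34	34	36	36	38	37	38	38	38	38	38	38	38	38	39	39	38	36	36
21	16	17	18	19	20	20	21	22	23	24	25	26	27	28	30	30	30	31	31	33	33	33	35	36	36	38	38	38	38	38	39	38	38	39	39	39	39	40	40	38	36
22	16	17	18	19	19	20	21	22	22	24	26	27	27	28	29	30	32	32	32	33	34	35	35	36	38	39	39	39	39	40	40	39	39	40	40	40	40	40	40	39	37
23	16	17	18	18	19	20	21	22	23	24	26	27	28	29	29	30	31	33	33	34	34	36	36	37	38	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	39
24	17	17	18	19	20	20	21	21	23	24	26	27	28	29	30	31	31	32	34	35	36	36	38	38	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
25	16	17	18	19	19	20	21	22	24	25	26	27	28	29	30	31	32	33	34	35	36	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
26	16	17	17	18	19	20	21	22	24	25	26	28	29	30	30	31	32	33	34	35	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
27	17	18	18	19	19	20	21	22	23	24	26	28	28	30	31	33	33	34	35	36	37	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
28	18	18	19	20	20	22	23	23	24	25	26	27	28	30	30	32	33	35	36	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
29	17	18	18	19	20	21	23	23	25	26	28	28	29	30	31	32	33	34	36	37	38	38	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
30	15	16	17	18	19	20	21	23	24	25	27	28	30	31	32	33	33	35	36	37	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
31	15	16	17	18	19	19	20	22	23	25	26	28	29	30	31	32	34	35	37	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
32	15	16	17	18	18	19	20	22	23	24	26	27	28	30	31	33	34	36	37	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
33	15	16	17	18	19	19	20	22	23	24	25	26	28	29	31	32	33	35	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
34	15	16	17	18	19	19	20	22	23	24	25	26	28	29	30	32	33	35	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
35	15	16	17	17	18	19	20	21	23	24	26	27	28	29	31	32	34	36	37	38	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
36	15	16	17	17	18	19	20	21	23	24	26	28	29	30	32	33	34	35	37	38	39	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
37	16	17	18	19	20	21	22	24	25	27	28	29	30	31	32	33	33	35	35	36	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40
38	17	18	19	20	21	23	24	25	26	27	27	28	29	29	30	31	32	34	35	37	38	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	39
39	19	19	19	20	20	21	21	22	23	25	26	27	28	29	30	31	32	34	35	36	36	38	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	39	37
40	17	18	18	19	20	20	21	21	23	24	26	28	29	29	30	32	32	32	34	35	36	36	37	39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	39	37	35
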