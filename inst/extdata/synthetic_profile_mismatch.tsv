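# synthetic mismatch quality-score profile (see match file header)
0	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37	38	39	40
0	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	7	8	9	10	11	12	14	15	16	17	18	19	20	21	22	23
1	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	9	10	11	12	13	14	16	17	18	19	20	20	21	22
2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	10	11	12	13	14	15	16	17	18	19	20	21	22
3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	5	6	7	8	9	10	12	13	14	15	16	17	18	19	20	21	21
4	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	7	8	9	10	11	12	14	15	16	17	18	19	19	20	21
5	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	8	9	10	11	12	13	14	15	16	17	18	19	20	21
6	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	10	11	12	13	14	15	16	17	18	19	20	20
7	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	4	5	6	7	8	9	10	12	13	14	15	16	17	18	18	19	20
8	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20
9	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	8	9	10	11	12	13	14	15	16	17	18	19	19
10	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	10	11	12	13	14	15	16	17	17	18	19
11	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	12	13	14	15	15	16	17	18	18
12	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	6	7	8	9	10	11	12	13	14	15	16	17	17	18
13	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	8	9	10	11	12	13	14	15	16	16	17	18
14	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	10	11	12	13	14	14	15	16	17	17
15	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	16	17
16	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	5	6	7	8	9	10	11	12	13	14	14	15	16	16
17	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	8	9	10	11	12	13	13	14	15	15	16
18	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	11	12	13	14	14	15	15
19	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	11	12	13	13	14	14	15
20	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	11	11	12	13	13	14	14
21	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	8	9	10	10	11	12	12	13	13	14
22	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	11	11	12	12	13	13
23	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	10	10	11	11	12	12	12
24	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	6	7	8	9	9	10	10	11	11	11	12
25	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	5	6	7	8	9	9	10	10	11	11	11
26	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	2	2	2	2	2	2	2	3	4	4	5	6	7	8	8	9	9	10	10	10	10
27	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	4	5	4	2	2	2	2	3	4	4	5	6	7	8	8	8	9	9	9	9	8
28	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	4	5	6	5	3	3	3	4	4	5	6	7	7	8	8	8	8	8	7	7
29	5	5	4	4	3	3	2	2	2	2	2	2	2	2	2	2	2	2	2	2	2	3	4	5	7	7	6	4	4	4	5	6	6	7	7	7	7	7	6	6	5
30	12	11	11	10	10	9	9	8	8	7	7	6	6	5	5	4	4	4	3	3	3	3	3	3	5	6	7	8	5	5	5	5	6	6	6	6	6	5	5	5	4
31	16	16	15	15	14	14	13	13	13	12	12	11	11	10	10	9	9	8	8	8	7	7	6	6	6	6	6	6	7	6	5	5	6	6	6	5	5	4	4	4	3
32	20	19	19	18	18	18	17	17	16	16	15	15	14	14	13	13	12	12	11	11	10	10	9	9	8	8	7	7	6	6	6	6	6	6	5	5	5	4	4	3	3
33	22	22	21	21	20	20	19	19	18	18	17	17	16	16	15	15	14	14	13	13	12	12	11	11	10	10	9	8	8	7	7	6	6	6	5	5	4	4	4	3	3
34	28	27	26	25	24	23	22	21	21	21	20	20	19	19	18	18	17	17	16	16	15	15	14	14	13	12	11	10	9	8	7	7	6	6	6	5	5	4	4	3	3
35	32	32	31	30	30	29	28	28	27	27	26	25	24	23	22	22	21	21	20	20	19	18	17	16	15	14	13	11	10	9	8	7	5	5	6	6	5	5	4	3	3
36	40	40	39	38	37	36	35	34	34	33	32	31	31	30	29	29	28	27	26	23	21	20	19	18	16	15	13	12	11	10	9	8	5	4	4	5	6	5	4	4	3
37	40	40	40	40	40	40	40	40	40	40	40	40	40	37	36	35	32	30	29	27	24	21	20	18	17	16	14	13	12	11	10	9	6	3	2	2	3	5	6	5	4
38	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	39	35	33	30	28	26	22	21	19	18	17	15	14	13	12	11	9	6	3	2	2	2	2	4	5	5
39	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	38	35	32	29	27	25	21	20	19	18	17	16	14	13	12	10	6	3	2	2	2	2	2	3	5
40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	40	36	33	30	28	26	22	21	20	19	18	17	15	14	13	10	7	4	2	2	2	2	2	2	2
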