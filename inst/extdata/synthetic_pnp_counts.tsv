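gene_id	egg	hpf24	hpf36	hpf48	hpf72	dpf4	dpf10	dpf15	mo1pre	mo1post	mo3	male	female
pnp001	0	0	0	0	0	0	0	3	0	0	0	0	0
pnp002	3	7	2	2	2	3	7	15	31	20	33	42	33
pnp003	2	1	0	2	0	1	5	5	16	11	23	52	36
pnp004	0	4	2	1	0	4	2	7	8	8	12	21	32
pnp005	0	2	6	3	14	48	45	41	31	6	2	2	2
pnp006	4	2	0	0	2	3	2	8	4	9	15	30	61
pnp007	3	4	5	5	13	42	59	55	28	5	5	2	2
pnp008	0	2	2	2	0	3	6	3	3	4	11	30	54
pnp009	4	15	28	11	23	47	19	20	3	1	0	2	3
pnp010	3	6	4	1	7	26	38	86	89	56	46	62	34
pnp011	2	9	13	10	20	42	20	7	3	2	0	2	1
pnp012	3	1	8	1	2	6	16	50	72	34	22	31	23
pnp013	0	1	3	2	3	3	1	4	12	4	10	20	20
pnp014	2	7	4	1	2	11	15	32	35	31	60	87	56
pnp015	528	1043	794	221	122	162	86	53	45	21	19	40	44
pnp016	3	6	5	3	0	16	22	62	93	52	65	122	86
pnp017	1	6	2	5	9	37	53	33	19	3	2	1	6
pnp018	2	5	7	2	4	30	82	96	110	44	33	28	13
pnp019	2	4	4	10	21	60	79	59	37	3	2	4	3
pnp020	7	34	53	26	17	33	22	11	2	1	1	2	1
pnp021	2	3	5	7	12	47	90	94	70	21	11	7	3
pnp022	3	1	2	0	4	6	21	33	54	29	25	28	17
pnp023	9	30	43	20	27	22	12	8	5	4	0	0	1
pnp024	3	1	2	2	1	11	28	41	54	14	14	16	7
pnp025	7	11	15	5	20	117	187	182	141	50	22	14	11
pnp026	1	3	2	0	1	1	1	7	8	4	6	37	38
pnp027	6	15	17	2	10	33	93	188	257	116	113	129	98
pnp028	1	4	2	3	5	20	33	30	10	6	3	1	1
pnp029	4	15	20	19	32	65	67	49	31	6	2	1	2
pnp030	5	6	6	8	11	43	82	126	154	49	43	38	24
pnp031	3	7	5	2	16	60	126	116	116	36	12	17	8
pnp032	3	3	14	3	1	5	2	0	1	0	1	0	2
pnp033	70	164	160	52	54	57	32	17	6	0	4	5	7
pnp034	8	25	48	39	65	225	191	114	54	9	5	6	6
pnp035	1	3	2	1	5	8	12	22	49	25	43	59	39
pnp036	8	31	28	14	20	28	16	6	2	3	1	2	1
pnp037	14	46	63	28	46	60	32	15	4	0	2	3	6
pnp038	3	0	7	3	10	38	49	57	42	6	3	11	0
pnp039	21	36	47	30	93	434	779	831	592	154	99	77	46
pnp040	1	24	51	13	28	82	43	30	14	3	0	6	5
pnp041	0	1	0	5	15	34	70	56	46	15	6	8	1
pnp042	5	12	15	6	24	47	28	15	8	0	1	3	2
pnp043	0	0	2	0	1	6	7	9	13	11	10	5	4
pnp044	0	2	1	0	3	15	33	42	29	7	5	7	2
pnp045	15	62	81	32	36	52	19	15	8	2	1	4	13
pnp046	1	1	2	1	2	11	5	23	36	19	18	19	20
pnp047	5	9	15	5	13	105	147	173	150	30	24	17	12
pnp048	3	22	38	30	61	185	147	89	33	6	8	6	7
pnp049	1	1	5	5	18	62	55	52	33	8	3	4	3
pnp050	1	1	1	0	2	5	17	25	48	18	27	26	19
pnp051	3	4	17	5	14	53	46	28	24	6	2	2	3
pnp052	25	50	33	10	2	2	3	3	0	2	1	0	1
pnp053	2	0	0	1	1	1	3	3	8	7	17	20	16
pnp054	6	13	26	19	48	158	203	177	93	19	11	12	10
pnp055	2	4	11	7	21	74	92	78	42	6	5	3	5
pnp056	0	2	3	0	0	9	22	22	36	11	12	9	6
pnp057	24	73	81	42	33	71	41	20	5	4	1	4	7
pnp058	2	1	0	1	0	7	8	21	27	16	24	40	25
pnp059	2	14	16	10	18	28	26	7	3	0	0	1	1
pnp060	3	4	20	17	24	99	122	87	72	18	1	7	5
pnp061	2	1	1	2	11	25	35	36	37	10	8	13	1
pnp062	22	57	39	21	23	19	6	6	2	1	4	3	2
pnp063	1	13	22	13	36	70	67	52	27	7	3	0	2
pnp064	0	1	5	2	5	8	6	10	1	0	0	1	1
pnp065	0	2	6	1	1	2	1	9	13	10	21	48	52
pnp066	0	0	0	0	0	0	2	7	3	0	0	1	1
pnp067	2	0	0	4	2	9	31	30	28	7	9	12	3
pnp068	3	5	4	2	4	13	20	43	62	19	29	36	26
pnp069	5	17	35	22	23	54	36	24	11	1	0	1	6
pnp070	1	5	1	0	2	5	3	1	3	0	0	1	0
pnp071	23	26	67	63	128	453	525	450	261	54	39	36	25
pnp072	1	3	0	2	5	13	50	54	47	20	11	17	5
pnp073	1	3	2	1	0	7	11	31	42	19	20	22	18
pnp074	0	0	1	2	2	5	13	14	24	7	5	2	0
pnp075	0	3	1	1	1	13	25	48	53	28	26	46	24
pnp076	2	0	0	1	1	10	12	20	42	20	6	19	12
pnp077	2	11	3	0	2	22	32	60	86	30	35	47	26
pnp078	1	5	13	9	17	63	76	60	35	6	5	3	5
pnp079	0	4	4	0	0	16	14	17	9	2	0	0	1
pnp080	0	1	0	0	0	0	1	0	4	1	1	3	0
pnp081	2	1	3	1	1	4	1	0	1	0	0	1	4
pnp082	1	0	2	0	1	1	2	1	1	1	0	0	2
pnp083	1	3	0	0	0	3	2	1	4	1	0	1	0
pnp084	1	0	2	0	0	2	2	0	3	0	0	0	1
pnp085	2	1	0	1	0	3	3	2	4	0	1	3	4
pnp086	0	0	3	0	0	0	4	2	2	1	0	0	1
pnp087	0	2	2	1	0	2	2	0	4	0	1	2	1
pnp088	0	1	2	1	1	0	1	0	0	1	1	3	4
pnp089	1	1	2	0	1	3	0	0	4	0	1	0	0
pnp090	0	1	2	1	1	4	4	2	1	1	1	1	0
pnp091	0	4	1	1	0	1	0	1	2	0	1	3	2
pnp092	0	0	1	1	0	0	0	0	0	0	0	2	0
pnp093	1	1	0	0	0	2	1	2	0	0	1	1	2
pnp094	1	4	3	0	1	4	2	0	4	0	0	3	4
pnp095	0	0	3	0	1	0	4	0	4	1	1	3	3
pnp096	0	2	0	0	1	0	1	1	0	0	1	3	3
pnp097	1	1	1	0	1	1	1	1	1	0	1	0	3
pnp098	0	4	3	1	0	1	4	1	0	0	0	0	1
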