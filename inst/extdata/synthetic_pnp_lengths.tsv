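gene_id	length
pnp001	871
pnp002	2986
pnp003	2574
pnp004	2664
pnp005	2582
pnp006	2320
pnp007	2871
pnp008	2587
pnp009	2603
pnp010	2799
pnp011	2892
pnp012	2588
pnp013	1838
pnp014	2111
pnp015	2609
pnp016	734
pnp017	2156
pnp018	2503
pnp019	2762
pnp020	1756
pnp021	1641
pnp022	1537
pnp023	1982
pnp024	1173
pnp025	1876
pnp026	821
pnp027	2510
pnp028	1671
pnp029	1377
pnp030	2021
pnp031	1691
pnp032	625
pnp033	1751
pnp034	1408
pnp035	2833
pnp036	1013
pnp037	2430
pnp038	1038
pnp039	2142
pnp040	2534
pnp041	2416
pnp042	1771
pnp043	2941
pnp044	1552
pnp045	1625
pnp046	1331
pnp047	2433
pnp048	1691
pnp049	2712
pnp050	2760
pnp051	2665
pnp052	2258
pnp053	2982
pnp054	1938
pnp055	1296
pnp056	1367
pnp057	1290
pnp058	2416
pnp059	2300
pnp060	1315
pnp061	2230
pnp062	918
pnp063	2502
pnp064	2581
pnp065	1461
pnp066	2229
pnp067	2402
pnp068	2587
pnp069	2394
pnp070	1628
pnp071	1689
pnp072	1071
pnp073	969
pnp074	1798
pnp075	1651
pnp076	2285
pnp077	2995
pnp078	1883
pnp079	2549
pnp080	1842
pnp081	683
pnp082	878
pnp083	2806
pnp084	2473
pnp085	2472
pnp086	1639
pnp087	2596
pnp088	1523
pnp089	1199
pnp090	2930
pnp091	742
pnp092	1603
pnp093	1788
pnp094	868
pnp095	2897
pnp096	1334
pnp097	1758
pnp098	2604
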