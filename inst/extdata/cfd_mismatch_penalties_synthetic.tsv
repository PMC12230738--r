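# Synthetic CFD-style mismatch penalty table (version 0.1.0).
# NOT the published Doench-2016 factors: a deterministic surrogate with the
# same structure -- factors in [0,1], matched bases = 1 (omitted here),
# PAM-proximal mismatches penalised more, transition and wobble-like
# mismatches tolerated more than transversions.
# factor(pos,g,o) = tol(g,o) * (1 - 0.75*(pos-1)/19); tol: transversion 0.35,
# transition 0.60, guide G vs off-target A 0.70.
position	guide_base	offtarget_base	factor
1	A	C	0.35
1	A	G	0.6
1	A	T	0.35
1	C	A	0.35
1	C	G	0.35
1	C	T	0.6
1	G	A	0.7
1	G	C	0.35
1	G	T	0.35
1	T	A	0.35
1	T	C	0.6
1	T	G	0.35
2	A	C	0.3362
2	A	G	0.5763
2	A	T	0.3362
2	C	A	0.3362
2	C	G	0.3362
2	C	T	0.5763
2	G	A	0.6724
2	G	C	0.3362
2	G	T	0.3362
2	T	A	0.3362
2	T	C	0.5763
2	T	G	0.3362
3	A	C	0.3224
3	A	G	0.5526
3	A	T	0.3224
3	C	A	0.3224
3	C	G	0.3224
3	C	T	0.5526
3	G	A	0.6447
3	G	C	0.3224
3	G	T	0.3224
3	T	A	0.3224
3	T	C	0.5526
3	T	G	0.3224
4	A	C	0.3086
4	A	G	0.5289
4	A	T	0.3086
4	C	A	0.3086
4	C	G	0.3086
4	C	T	0.5289
4	G	A	0.6171
4	G	C	0.3086
4	G	T	0.3086
4	T	A	0.3086
4	T	C	0.5289
4	T	G	0.3086
5	A	C	0.2947
5	A	G	0.5053
5	A	T	0.2947
5	C	A	0.2947
5	C	G	0.2947
5	C	T	0.5053
5	G	A	0.5895
5	G	C	0.2947
5	G	T	0.2947
5	T	A	0.2947
5	T	C	0.5053
5	T	G	0.2947
6	A	C	0.2809
6	A	G	0.4816
6	A	T	0.2809
6	C	A	0.2809
6	C	G	0.2809
6	C	T	0.4816
6	G	A	0.5618
6	G	C	0.2809
6	G	T	0.2809
6	T	A	0.2809
6	T	C	0.4816
6	T	G	0.2809
7	A	C	0.2671
7	A	G	0.4579
7	A	T	0.2671
7	C	A	0.2671
7	C	G	0.2671
7	C	T	0.4579
7	G	A	0.5342
7	G	C	0.2671
7	G	T	0.2671
7	T	A	0.2671
7	T	C	0.4579
7	T	G	0.2671
8	A	C	0.2533
8	A	G	0.4342
8	A	T	0.2533
8	C	A	0.2533
8	C	G	0.2533
8	C	T	0.4342
8	G	A	0.5066
8	G	C	0.2533
8	G	T	0.2533
8	T	A	0.2533
8	T	C	0.4342
8	T	G	0.2533
9	A	C	0.2395
9	A	G	0.4105
9	A	T	0.2395
9	C	A	0.2395
9	C	G	0.2395
9	C	T	0.4105
9	G	A	0.4789
9	G	C	0.2395
9	G	T	0.2395
9	T	A	0.2395
9	T	C	0.4105
9	T	G	0.2395
10	A	C	0.2257
10	A	G	0.3868
10	A	T	0.2257
10	C	A	0.2257
10	C	G	0.2257
10	C	T	0.3868
10	G	A	0.4513
10	G	C	0.2257
10	G	T	0.2257
10	T	A	0.2257
10	T	C	0.3868
10	T	G	0.2257
11	A	C	0.2118
11	A	G	0.3632
11	A	T	0.2118
11	C	A	0.2118
11	C	G	0.2118
11	C	T	0.3632
11	G	A	0.4237
11	G	C	0.2118
11	G	T	0.2118
11	T	A	0.2118
11	T	C	0.3632
11	T	G	0.2118
12	A	C	0.198
12	A	G	0.3395
12	A	T	0.198
12	C	A	0.198
12	C	G	0.198
12	C	T	0.3395
12	G	A	0.3961
12	G	C	0.198
12	G	T	0.198
12	T	A	0.198
12	T	C	0.3395
12	T	G	0.198
13	A	C	0.1842
13	A	G	0.3158
13	A	T	0.1842
13	C	A	0.1842
13	C	G	0.1842
13	C	T	0.3158
13	G	A	0.3684
13	G	C	0.1842
13	G	T	0.1842
13	T	A	0.1842
13	T	C	0.3158
13	T	G	0.1842
14	A	C	0.1704
14	A	G	0.2921
14	A	T	0.1704
14	C	A	0.1704
14	C	G	0.1704
14	C	T	0.2921
14	G	A	0.3408
14	G	C	0.1704
14	G	T	0.1704
14	T	A	0.1704
14	T	C	0.2921
14	T	G	0.1704
15	A	C	0.1566
15	A	G	0.2684
15	A	T	0.1566
15	C	A	0.1566
15	C	G	0.1566
15	C	T	0.2684
15	G	A	0.3132
15	G	C	0.1566
15	G	T	0.1566
15	T	A	0.1566
15	T	C	0.2684
15	T	G	0.1566
16	A	C	0.1428
16	A	G	0.2447
16	A	T	0.1428
16	C	A	0.1428
16	C	G	0.1428
16	C	T	0.2447
16	G	A	0.2855
16	G	C	0.1428
16	G	T	0.1428
16	T	A	0.1428
16	T	C	0.2447
16	T	G	0.1428
17	A	C	0.1289
17	A	G	0.2211
17	A	T	0.1289
17	C	A	0.1289
17	C	G	0.1289
17	C	T	0.2211
17	G	A	0.2579
17	G	C	0.1289
17	G	T	0.1289
17	T	A	0.1289
17	T	C	0.2211
17	T	G	0.1289
18	A	C	0.1151
18	A	G	0.1974
18	A	T	0.1151
18	C	A	0.1151
18	C	G	0.1151
18	C	T	0.1974
18	G	A	0.2303
18	G	C	0.1151
18	G	T	0.1151
18	T	A	0.1151
18	T	C	0.1974
18	T	G	0.1151
19	A	C	0.1013
19	A	G	0.1737
19	A	T	0.1013
19	C	A	0.1013
19	C	G	0.1013
19	C	T	0.1737
19	G	A	0.2026
19	G	C	0.1013
19	G	T	0.1013
19	T	A	0.1013
19	T	C	0.1737
19	T	G	0.1013
20	A	C	0.0875
20	A	G	0.15
20	A	T	0.0875
20	C	A	0.0875
20	C	G	0.0875
20	C	T	0.15
20	G	A	0.175
20	G	C	0.0875
20	G	T	0.0875
20	T	A	0.0875
20	T	C	0.15
20	T	G	0.0875
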