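position	guide_base	target_base	weight
1	A	C	0.5252
1	A	G	0.8595
1	A	T	0.5252
1	C	A	0.3342
1	C	G	0.3342
1	C	T	0.8595
1	G	A	0.8595
1	G	C	0.5252
1	G	T	0.5252
1	T	A	0.3342
1	T	C	0.8595
1	T	G	0.3342
2	A	C	0.5005
2	A	G	0.819
2	A	T	0.5005
2	C	A	0.3185
2	C	G	0.3185
2	C	T	0.819
2	G	A	0.819
2	G	C	0.5005
2	G	T	0.5005
2	T	A	0.3185
2	T	C	0.819
2	T	G	0.3185
3	A	C	0.4758
3	A	G	0.7785
3	A	T	0.4758
3	C	A	0.3027
3	C	G	0.3027
3	C	T	0.7785
3	G	A	0.7785
3	G	C	0.4758
3	G	T	0.4758
3	T	A	0.3027
3	T	C	0.7785
3	T	G	0.3027
4	A	C	0.451
4	A	G	0.738
4	A	T	0.451
4	C	A	0.287
4	C	G	0.287
4	C	T	0.738
4	G	A	0.738
4	G	C	0.451
4	G	T	0.451
4	T	A	0.287
4	T	C	0.738
4	T	G	0.287
5	A	C	0.4263
5	A	G	0.6975
5	A	T	0.4263
5	C	A	0.2712
5	C	G	0.2712
5	C	T	0.6975
5	G	A	0.6975
5	G	C	0.4263
5	G	T	0.4263
5	T	A	0.2712
5	T	C	0.6975
5	T	G	0.2712
6	A	C	0.4015
6	A	G	0.657
6	A	T	0.4015
6	C	A	0.2555
6	C	G	0.2555
6	C	T	0.657
6	G	A	0.657
6	G	C	0.4015
6	G	T	0.4015
6	T	A	0.2555
6	T	C	0.657
6	T	G	0.2555
7	A	C	0.3768
7	A	G	0.6165
7	A	T	0.3768
7	C	A	0.2397
7	C	G	0.2397
7	C	T	0.6165
7	G	A	0.6165
7	G	C	0.3768
7	G	T	0.3768
7	T	A	0.2397
7	T	C	0.6165
7	T	G	0.2397
8	A	C	0.352
8	A	G	0.576
8	A	T	0.352
8	C	A	0.224
8	C	G	0.224
8	C	T	0.576
8	G	A	0.576
8	G	C	0.352
8	G	T	0.352
8	T	A	0.224
8	T	C	0.576
8	T	G	0.224
9	A	C	0.3272
9	A	G	0.5355
9	A	T	0.3272
9	C	A	0.2082
9	C	G	0.2082
9	C	T	0.5355
9	G	A	0.5355
9	G	C	0.3272
9	G	T	0.3272
9	T	A	0.2082
9	T	C	0.5355
9	T	G	0.2082
10	A	C	0.3025
10	A	G	0.495
10	A	T	0.3025
10	C	A	0.1925
10	C	G	0.1925
10	C	T	0.495
10	G	A	0.495
10	G	C	0.3025
10	G	T	0.3025
10	T	A	0.1925
10	T	C	0.495
10	T	G	0.1925
11	A	C	0.2778
11	A	G	0.4545
11	A	T	0.2778
11	C	A	0.1767
11	C	G	0.1767
11	C	T	0.4545
11	G	A	0.4545
11	G	C	0.2778
11	G	T	0.2778
11	T	A	0.1767
11	T	C	0.4545
11	T	G	0.1767
12	A	C	0.253
12	A	G	0.414
12	A	T	0.253
12	C	A	0.161
12	C	G	0.161
12	C	T	0.414
12	G	A	0.414
12	G	C	0.253
12	G	T	0.253
12	T	A	0.161
12	T	C	0.414
12	T	G	0.161
13	A	C	0.2283
13	A	G	0.3735
13	A	T	0.2283
13	C	A	0.1452
13	C	G	0.1452
13	C	T	0.3735
13	G	A	0.3735
13	G	C	0.2283
13	G	T	0.2283
13	T	A	0.1452
13	T	C	0.3735
13	T	G	0.1452
14	A	C	0.2035
14	A	G	0.333
14	A	T	0.2035
14	C	A	0.1295
14	C	G	0.1295
14	C	T	0.333
14	G	A	0.333
14	G	C	0.2035
14	G	T	0.2035
14	T	A	0.1295
14	T	C	0.333
14	T	G	0.1295
15	A	C	0.1788
15	A	G	0.2925
15	A	T	0.1788
15	C	A	0.1138
15	C	G	0.1138
15	C	T	0.2925
15	G	A	0.2925
15	G	C	0.1788
15	G	T	0.1788
15	T	A	0.1138
15	T	C	0.2925
15	T	G	0.1138
16	A	C	0.154
16	A	G	0.252
16	A	T	0.154
16	C	A	0.098
16	C	G	0.098
16	C	T	0.252
16	G	A	0.252
16	G	C	0.154
16	G	T	0.154
16	T	A	0.098
16	T	C	0.252
16	T	G	0.098
17	A	C	0.1292
17	A	G	0.2115
17	A	T	0.1292
17	C	A	0.0822
17	C	G	0.0822
17	C	T	0.2115
17	G	A	0.2115
17	G	C	0.1292
17	G	T	0.1292
17	T	A	0.0822
17	T	C	0.2115
17	T	G	0.0822
18	A	C	0.1045
18	A	G	0.171
18	A	T	0.1045
18	C	A	0.0665
18	C	G	0.0665
18	C	T	0.171
18	G	A	0.171
18	G	C	0.1045
18	G	T	0.1045
18	T	A	0.0665
18	T	C	0.171
18	T	G	0.0665
19	A	C	0.0798
19	A	G	0.1305
19	A	T	0.0798
19	C	A	0.0508
19	C	G	0.0508
19	C	T	0.1305
19	G	A	0.1305
19	G	C	0.0798
19	G	T	0.0798
19	T	A	0.0508
19	T	C	0.1305
19	T	G	0.0508
20	A	C	0.055
20	A	G	0.09
20	A	T	0.055
20	C	A	0.035
20	C	G	0.035
20	C	T	0.09
20	G	A	0.09
20	G	C	0.055
20	G	T	0.055
20	T	A	0.035
20	T	C	0.09
20	T	G	0.035
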