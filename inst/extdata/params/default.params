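# costruct nearest-neighbor parameter bundle
#
# All energies are in kcal/mol and must sit on a 0.1 kcal/mol grid; the
# package resolves them to integer tenths internally so that dynamic-
# programming comparisons are exact.
#
# Sections:
#   [scalars]        one "key value" per line
#   [stack]          "closing_pair stacked_pair energy"; a pair XY is the
#                    5' base X paired to the 3' base Y of the closing pair,
#                    the stacked pair is the next pair inward.  All 36
#                    ordered combinations of the six canonical pairs must
#                    be present.  The table is symmetric under reading the
#                    stack from the other strand:
#                    stack(XY,WZ) == stack(ZW,YX).
#   [hairpin_init]   "loopsize energy" for loop sizes 3..30
#   [bulge_init]     "length energy" for lengths 1..30
#   [internal_init]  "size energy" for total internal loop sizes 2..30
#
# Loop initiations beyond size 30 are extrapolated as
#   init(n) = init(30) + log_extrapolation * ln(n/30).

[scalars]
au_gu_end_penalty 0.5
mbl_closure 3.4
mbl_branch 0.4
mbl_unpaired 0.0
gap_penalty 0.4
domain_opening 0.5
domain_elongation 0.1
asymmetry_coef 0.5
asymmetry_max 3.0
log_extrapolation 1.1
max_internal_side 20
max_stackII_extension 5
min_hairpin 3

[stack]
AU AU -0.9
AU CG -2.2
AU GC -2.1
AU UA -1.1
AU GU -0.6
AU UG -1.4
CG AU -2.1
CG CG -3.3
CG GC -2.4
CG UA -2.1
CG GU -1.4
CG UG -2.1
GC AU -2.4
GC CG -3.4
GC GC -3.3
GC UA -2.2
GC GU -1.5
GC UG -2.5
UA AU -1.3
UA CG -2.4
UA GC -2.1
UA UA -0.9
UA GU -1.0
UA UG -1.3
GU AU -1.3
GU CG -2.5
GU GC -2.1
GU UA -1.4
GU GU -0.5
GU UG 1.3
UG AU -1.0
UG CG -1.5
UG GC -1.4
UG UA -0.6
UG GU 0.3
UG UG -0.5

[hairpin_init]
3 5.4
4 5.6
5 5.7
6 5.4
7 6.0
8 5.5
9 6.4
10 6.5
11 6.6
12 6.7
13 6.8
14 6.9
15 7.0
16 7.0
17 7.1
18 7.2
19 7.2
20 7.3
21 7.3
22 7.4
23 7.4
24 7.5
25 7.5
26 7.6
27 7.6
28 7.6
29 7.7
30 7.7

[bulge_init]
1 3.8
2 2.8
3 3.2
4 3.6
5 4.0
6 4.4
7 4.6
8 4.7
9 4.8
10 5.0
11 5.1
12 5.2
13 5.3
14 5.3
15 5.4
16 5.5
17 5.5
18 5.6
19 5.7
20 5.7
21 5.8
22 5.8
23 5.9
24 5.9
25 6.0
26 6.0
27 6.1
28 6.1
29 6.1
30 6.2

[internal_init]
2 1.5
3 1.6
4 1.7
5 1.8
6 2.0
7 2.2
8 2.3
9 2.4
10 2.5
11 2.6
12 2.7
13 2.8
14 2.9
15 3.0
16 3.0
17 3.1
18 3.2
19 3.2
20 3.3
21 3.3
22 3.4
23 3.4
24 3.5
25 3.5
26 3.6
27 3.6
28 3.6
29 3.7
30 3.7
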