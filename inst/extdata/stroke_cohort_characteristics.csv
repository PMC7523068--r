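patient,gender,age_years,dominant_hand,post_stroke_weeks,paretic_side,uefms
1,M,74,R,4,L,29
2,M,69,R,3,L,30
3,M,54,R,22,L,24
4,F,76,R,8,L,42
5,M,49,R,16,L,48
6,M,23,L,18,R,57
7,F,70,R,10,L,64
8,M,59,R,6,R,15
9,M,61,R,5,L,39
10,M,62,R,8,L,38
11,F,34,R,11,R,15
12,M,48,R,7,R,33
13,F,76,R,20,L,36
14,F,72,R,7,R,51
15,F,33,R,9,R,22
16,M,46,R,3,R,54
17,M,76,R,14,R,36
18,M,53,R,7,R,28
19,F,47,R,10,L,31
20,M,65,R,153,L,28
21,M,35,R,3,R,48
22,F,38,R,10,R,48
23,M,33,R,11,R,65
24,M,69,L,15,L,53
25,M,67,L,4,L,42
26,M,43,R,5,L,44
27,M,52,R,20,L,23
28,M,59,R,5,L,55
29,F,70,R,8,R,58
30,M,22,R,66,R,64
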