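table_row,sp_id,host,mean_activity_U_per_mL,sd_activity_U_per_mL,relative_activity_pct,relative_sd_pct
1,Epr,C_glutamicum,13.1,0.8,100.0,5.8
2,YwfM,C_glutamicum,11.2,1.4,85.5,10.4
3,Bpr,C_glutamicum,11.1,1.0,84.8,7.9
4,Vpr,C_glutamicum,10.5,0.1,80.2,0.6
5,YkvV,C_glutamicum,9.4,1.9,72.0,14.1
6,YurI,C_glutamicum,9.4,0.6,71.9,4.9
7,YxiT,C_glutamicum,9.4,0.3,71.4,2.0
8,LipB,C_glutamicum,9.2,2.1,70.2,15.9
9,YurI,C_glutamicum,8.6,0.6,65.6,4.4
10,YckD,C_glutamicum,8.5,2.3,64.9,17.7
11,YfjS,C_glutamicum,8.0,0.3,60.8,2.2
12,Epr,C_glutamicum,7.8,1.6,59.8,12.1
13,YxaK,C_glutamicum,7.8,1.2,59.5,9.1
14,Csn,C_glutamicum,7.5,2.0,57.4,15.5
15,YxaK,C_glutamicum,8.0,2.3,60.9,17.5
16,YndA,C_glutamicum,7.2,3.5,55.0,27.0
17,YxaK,C_glutamicum,7.1,0.3,54.0,2.4
18,YbdN,C_glutamicum,6.9,1.2,52.4,9.1
19,YobB,C_glutamicum,6.7,0.6,50.9,4.8
20,YndA,C_glutamicum,6.2,3.6,47.2,27.3
21,YkvV,C_glutamicum,6.1,0.6,46.5,4.6
22,YurI,C_glutamicum,5.6,0.9,42.7,6.5
23,YwtD,C_glutamicum,5.9,1.1,45.2,8.6
24,YddT,C_glutamicum,5.7,0.5,43.6,4.0
25,YbbE,C_glutamicum,5.6,0.0,42.7,0.1
26,Mdr,C_glutamicum,5.5,0.1,42.1,0.5
27,YobV,C_glutamicum,5.0,0.2,38.5,1.5
28,YvpA,C_glutamicum,5.0,0.5,38.2,3.9
29,YwmC,C_glutamicum,4.6,0.2,35.2,1.2
30,YbbE,C_glutamicum,4.5,0.5,34.4,4.0
31,YwmD,C_glutamicum,4.5,0.4,34.4,2.8
32,YckD,C_glutamicum,4.4,0.1,33.9,0.7
33,YvgO,C_glutamicum,3.6,0.3,27.5,2.4
34,TasA,C_glutamicum,3.4,3.0,26.1,22.5
35,YqxI,C_glutamicum,3.2,0.2,24.7,1.4
36,YndA,C_glutamicum,3.2,0.6,24.3,4.7
37,YogH,C_glutamicum,2.7,1.7,20.4,12.9
38,YfkN,C_glutamicum,2.1,0.0,16.3,0.2
39,LytC,C_glutamicum,2.1,1.3,16.2,9.6
40,WprA,C_glutamicum,2.1,1.7,15.8,13.0
41,YobV,C_glutamicum,2.0,1.3,15.2,9.8
42,YbdN,C_glutamicum,1.9,1.1,14.9,8.6
43,Pel,C_glutamicum,1.9,0.5,14.5,3.7
44,YycP,C_glutamicum,1.9,2.1,14.2,16.3
45,YogH,C_glutamicum,1.7,0.3,12.9,2.3
46,YvpB,C_glutamicum,1.6,1.7,12.2,13.2
47,AmyE,C_glutamicum,1.5,0.2,11.5,1.8
48,YogH,C_glutamicum,1.3,0.1,10.1,0.5
49,TasA,C_glutamicum,1.2,0.2,9.5,1.5
50,AmyE,C_glutamicum,1.0,0.1,7.8,0.8
51,AmyE,C_glutamicum,0.9,0.2,7.2,1.8
52,YbbE,C_glutamicum,0.9,0.5,6.9,4.1
53,YogH,C_glutamicum,0.9,0.2,6.6,1.4
54,YycP,C_glutamicum,0.8,0.8,6.3,6.1
55,DacF,C_glutamicum,0.8,0.2,5.8,1.2
56,RpmG,C_glutamicum,0.7,0.6,5.4,4.6
57,YycP,C_glutamicum,0.7,0.7,5.4,5.6
58,YwgB,C_glutamicum,0.7,0.2,5.3,1.8
59,YwtD,C_glutamicum,0.5,0.3,3.7,2.4
60,YdbK,C_glutamicum,0.4,0.1,3.0,0.4
61,YwtF,C_glutamicum,0.3,0.0,2.5,0.3
62,YwgB,C_glutamicum,0.3,0.1,2.5,0.9
63,YqzC,C_glutamicum,0.3,0.1,2.0,0.5
64,YvpB,C_glutamicum,0.0,0.0,0.3,0.1
1,Epr,B_subtilis,4.7,NA,100.0,NA
2,YwfM,B_subtilis,0.4,NA,7.7,NA
3,Bpr,B_subtilis,3.0,NA,63.6,NA
4,Vpr,B_subtilis,2.2,NA,47.1,NA
5,YkvV,B_subtilis,1.0,NA,21.8,NA
6,YurI,B_subtilis,1.9,NA,41.5,NA
7,YxiT,B_subtilis,0.9,NA,19.3,NA
8,LipB,B_subtilis,1.6,NA,34.7,NA
9,YurI,B_subtilis,1.9,NA,41.5,NA
10,YckD,B_subtilis,2.8,NA,59.7,NA
11,YfjS,B_subtilis,0.5,NA,10.5,NA
12,Epr,B_subtilis,4.7,NA,100.0,NA
13,YxaK,B_subtilis,0.0,NA,0.0,NA
14,Csn,B_subtilis,3.4,NA,71.7,NA
15,YxaK,B_subtilis,0.0,NA,0.0,NA
16,YndA,B_subtilis,0.5,NA,11.1,NA
17,YxaK,B_subtilis,0.0,NA,0.0,NA
18,YbdN,B_subtilis,2.5,NA,53.7,NA
19,YobB,B_subtilis,2.5,NA,53.3,NA
20,YndA,B_subtilis,0.5,NA,11.1,NA
21,YkvV,B_subtilis,1.0,NA,21.8,NA
22,YurI,B_subtilis,1.9,NA,41.5,NA
23,YwtD,B_subtilis,0.3,NA,5.4,NA
24,YddT,B_subtilis,2.4,NA,51.6,NA
25,YbbE,B_subtilis,2.1,NA,44.8,NA
26,Mdr,B_subtilis,0.4,NA,8.8,NA
27,YobV,B_subtilis,0.0,NA,0.0,NA
28,YvpA,B_subtilis,1.9,NA,40.0,NA
29,YwmC,B_subtilis,1.2,NA,25.1,NA
30,YbbE,B_subtilis,2.1,NA,44.8,NA
31,YwmD,B_subtilis,0.3,NA,5.6,NA
32,YckD,B_subtilis,2.8,NA,59.7,NA
33,YvgO,B_subtilis,0.0,NA,0.0,NA
34,TasA,B_subtilis,0.3,NA,6.2,NA
35,YqxI,B_subtilis,1.4,NA,30.2,NA
36,YndA,B_subtilis,0.5,NA,11.1,NA
37,YogH,B_subtilis,0.0,NA,0.0,NA
38,YfkN,B_subtilis,0.2,NA,4.5,NA
39,LytC,B_subtilis,0.9,NA,19.3,NA
40,WprA,B_subtilis,0.1,NA,2.6,NA
41,YobV,B_subtilis,0.0,NA,0.0,NA
42,YbdN,B_subtilis,2.5,NA,53.7,NA
43,Pel,B_subtilis,2.7,NA,57.2,NA
44,YycP,B_subtilis,0.0,NA,0.0,NA
45,YogH,B_subtilis,0.0,NA,0.0,NA
46,YvpB,B_subtilis,0.0,NA,0.0,NA
47,AmyE,B_subtilis,0.7,NA,14.3,NA
48,YogH,B_subtilis,0.0,NA,0.0,NA
49,TasA,B_subtilis,0.3,NA,6.2,NA
50,AmyE,B_subtilis,0.7,NA,14.3,NA
51,AmyE,B_subtilis,0.7,NA,14.3,NA
52,YbbE,B_subtilis,2.1,NA,44.8,NA
53,YogH,B_subtilis,0.0,NA,0.0,NA
54,YycP,B_subtilis,0.0,NA,0.0,NA
55,DacF,B_subtilis,0.1,NA,3.0,NA
56,RpmG,B_subtilis,0.1,NA,3.0,NA
57,YycP,B_subtilis,0.0,NA,0.0,NA
58,YwgB,B_subtilis,0.0,NA,0.0,NA
59,YwtD,B_subtilis,0.3,NA,5.4,NA
60,YdbK,B_subtilis,0.2,NA,4.7,NA
61,YwtF,B_subtilis,0.0,NA,0.0,NA
62,YwgB,B_subtilis,0.0,NA,0.0,NA
63,YqzC,B_subtilis,0.0,NA,0.0,NA
64,YvpB,B_subtilis,0.0,NA,0.0,NA
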