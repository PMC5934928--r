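item,raw,score
1,1,100
1,2,75
1,3,50
1,4,25
1,5,0
2,1,100
2,2,75
2,3,50
2,4,25
2,5,0
3,1,0
3,2,50
3,3,100
4,1,0
4,2,50
4,3,100
5,1,0
5,2,50
5,3,100
6,1,0
6,2,50
6,3,100
7,1,0
7,2,50
7,3,100
8,1,0
8,2,50
8,3,100
9,1,0
9,2,50
9,3,100
10,1,0
10,2,50
10,3,100
11,1,0
11,2,50
11,3,100
12,1,0
12,2,50
12,3,100
13,1,0
13,2,100
14,1,0
14,2,100
15,1,0
15,2,100
16,1,0
16,2,100
17,1,0
17,2,100
18,1,0
18,2,100
19,1,0
19,2,100
20,1,100
20,2,75
20,3,50
20,4,25
20,5,0
21,1,100
21,2,80
21,3,60
21,4,40
21,5,20
21,6,0
22,1,100
22,2,75
22,3,50
22,4,25
22,5,0
23,1,100
23,2,80
23,3,60
23,4,40
23,5,20
23,6,0
24,1,0
24,2,20
24,3,40
24,4,60
24,5,80
24,6,100
25,1,0
25,2,20
25,3,40
25,4,60
25,5,80
25,6,100
26,1,100
26,2,80
26,3,60
26,4,40
26,5,20
26,6,0
27,1,100
27,2,80
27,3,60
27,4,40
27,5,20
27,6,0
28,1,0
28,2,20
28,3,40
28,4,60
28,5,80
28,6,100
29,1,0
29,2,20
29,3,40
29,4,60
29,5,80
29,6,100
30,1,100
30,2,80
30,3,60
30,4,40
30,5,20
30,6,0
31,1,0
31,2,20
31,3,40
31,4,60
31,5,80
31,6,100
32,1,0
32,2,25
32,3,50
32,4,75
32,5,100
33,1,0
33,2,25
33,3,50
33,4,75
33,5,100
34,1,100
34,2,75
34,3,50
34,4,25
34,5,0
35,1,0
35,2,25
35,3,50
35,4,75
35,5,100
36,1,100
36,2,75
36,3,50
36,4,25
36,5,0
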