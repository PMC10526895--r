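i,j
1,23
1,24
1,25
1,29
2,10
2,28
2,30
3,4
3,5
3,12
3,16
3,17
3,28
3,30
4,16
4,26
5,7
5,12
5,30
6,8
6,13
6,15
6,19
7,10
7,12
7,14
7,22
7,30
8,13
8,19
8,23
8,24
8,25
9,11
9,18
9,20
9,22
10,21
10,22
10,27
10,28
10,30
11,14
11,18
11,22
12,14
12,16
13,15
13,21
13,24
14,16
14,18
14,22
14,26
15,19
15,20
15,21
15,22
16,26
17,27
17,28
17,29
18,20
18,26
19,23
20,22
21,22
21,24
21,27
21,29
23,25
24,25
24,29
27,28
27,29
28,30
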