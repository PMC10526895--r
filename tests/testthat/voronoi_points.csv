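id,x_deg,y_deg
1,9.889093,6.799935
2,3.977455,2.637199
3,1.156978,1.857143
4,0.697487,1.851432
5,2.437494,3.792967
6,7.920104,8.470244
7,3.400624,4.980761
8,9.720625,7.905856
9,1.658555,8.384639
10,4.591037,4.569039
11,1.717481,7.994758
12,2.314771,3.819431
13,7.728119,7.597012
14,0.963015,4.367756
15,4.534478,9.042177
16,0.847007,3.195349
17,5.606659,0.825691
18,0.087046,8.162891
19,9.857371,8.984762
20,3.165848,9.664964
21,6.394489,5.730689
22,2.952232,7.200795
23,9.967037,7.740586
24,9.060213,6.277608
25,9.887391,7.229893
26,0.656457,3.868313
27,6.270388,1.627908
28,4.90475,1.872283
29,9.710244,3.912495
30,3.622208,2.739012
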