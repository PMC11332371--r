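"id","visit","A","L","P","event_time","event_indicator"
1,0,0,0.2957,0.0988,6,0
1,1,0,0.0541,0.0988,6,0
1,2,1,-0.1042,0.0988,6,0
1,3,1,-0.7477,0.0988,6,0
1,4,1,-1.3224,0.0988,6,0
1,5,1,-1.3917,0.0988,6,0
2,0,1,-0.1277,0.2715,5.445,0
2,1,1,-0.1373,0.2715,5.445,0
2,2,1,-0.2466,0.2715,5.445,0
2,3,1,-0.7662,0.2715,5.445,0
2,4,1,-0.9831,0.2715,5.445,0
2,5,1,-0.7047,0.2715,5.445,0
3,0,0,0.1201,0.7665,1.796,1
3,1,1,0.0011,0.7665,1.796,1
4,0,0,-0.6493,0.2246,6,0
4,1,0,0.1407,0.2246,6,0
4,2,0,-0.0883,0.2246,6,0
4,3,0,-0.4341,0.2246,6,0
4,4,1,-0.8874,0.2246,6,0
4,5,1,-0.8044,0.2246,6,0
5,0,1,-1.8436,0.2024,6,0
5,1,1,-1.3964,0.2024,6,0
5,2,1,-1.8824,0.2024,6,0
5,3,1,-1.6083,0.2024,6,0
5,4,1,-1.1911,0.2024,6,0
5,5,1,-1.3056,0.2024,6,0
6,0,0,0.2314,0.3033,0.414,1
7,0,0,-0.4158,0.2408,0.093,1
8,0,0,-1.5902,0.3711,6,0
8,1,0,-1.4907,0.3711,6,0
8,2,0,-1.6242,0.3711,6,0
8,3,0,-0.9009,0.3711,6,0
8,4,0,-1.392,0.3711,6,0
8,5,0,-0.9829,0.3711,6,0
9,0,0,-0.7911,0.5506,6,0
9,1,0,-1.5171,0.5506,6,0
9,2,0,-1.7457,0.5506,6,0
9,3,0,-1.5853,0.5506,6,0
9,4,0,-1.0415,0.5506,6,0
9,5,0,-1.2203,0.5506,6,0
10,0,0,0.2015,0.7471,0.103,1
11,0,0,-0.654,0.3688,3.545,1
11,1,0,-0.092,0.3688,3.545,1
11,2,0,-1.3092,0.3688,3.545,1
11,3,0,-0.8084,0.3688,3.545,1
12,0,1,0.2426,0.1157,3.577,1
12,1,1,-0.0932,0.1157,3.577,1
12,2,1,-0.3739,0.1157,3.577,1
12,3,1,-0.984,0.1157,3.577,1
13,0,0,-1.7523,0.2424,6,0
13,1,0,-1.1869,0.2424,6,0
13,2,0,0.2006,0.2424,6,0
13,3,0,0.2153,0.2424,6,0
13,4,1,-0.0368,0.2424,6,0
13,5,1,-0.0063,0.2424,6,0
14,0,0,-0.0799,0.2139,5.169,1
14,1,0,0.3439,0.2139,5.169,1
14,2,0,0.3428,0.2139,5.169,1
14,3,0,0.3175,0.2139,5.169,1
14,4,0,0.4568,0.2139,5.169,1
14,5,0,0.089,0.2139,5.169,1
15,0,0,-0.1458,0.5051,1.85,0
15,1,0,-0.4921,0.5051,1.85,0
16,0,0,-1.1414,0.3912,6,0
16,1,0,-1.0292,0.3912,6,0
16,2,0,-0.6429,0.3912,6,0
16,3,0,0.2889,0.3912,6,0
16,4,0,1.0659,0.3912,6,0
16,5,1,0.5236,0.3912,6,0
17,0,0,1.5427,0.7221,0.643,1
18,0,1,1.2707,0.5199,1.427,1
18,1,1,1.2273,0.5199,1.427,1
19,0,0,0.17,0.0385,5.8,0
19,1,0,-0.0392,0.0385,5.8,0
19,2,0,-1.3968,0.0385,5.8,0
19,3,0,-1.1549,0.0385,5.8,0
19,4,0,-1.1516,0.0385,5.8,0
19,5,0,-0.7806,0.0385,5.8,0
20,0,0,0.1981,0.3372,6,0
20,1,0,-0.3542,0.3372,6,0
20,2,1,-1.402,0.3372,6,0
20,3,1,-1.7526,0.3372,6,0
20,4,1,-1.6257,0.3372,6,0
20,5,1,-0.8561,0.3372,6,0
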