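"id","strategy","horizon","risk"
1,"never",5,0.539
2,"never",5,0.5101
3,"never",5,0.6423
4,"never",5,0.4231
5,"never",5,0.2603
6,"never",5,0.5699
7,"never",5,0.4609
8,"never",5,0.3192
9,"never",5,0.4665
10,"never",5,0.6499
11,"never",5,0.4508
12,"never",5,0.5345
13,"never",5,0.2774
14,"never",5,0.5058
15,"never",5,0.5539
16,"never",5,0.3842
17,"never",5,0.8027
18,"never",5,0.7462
19,"never",5,0.5082
20,"never",5,0.5717
1,"always",5,0.3674
2,"always",5,0.3409
3,"always",5,0.4713
4,"always",5,0.267
5,"always",5,0.1488
6,"always",5,0.3969
7,"always",5,0.298
8,"always",5,0.1889
9,"always",5,0.3028
10,"always",5,0.4797
11,"always",5,0.2896
12,"always",5,0.3631
13,"always",5,0.1601
14,"always",5,0.337
15,"always",5,0.3814
16,"always",5,0.2365
17,"always",5,0.6689
18,"always",5,0.5935
19,"always",5,0.3391
20,"always",5,0.3986
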