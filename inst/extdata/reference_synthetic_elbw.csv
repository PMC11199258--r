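# synthetic p50 reference (q_curve defaults); NOT published reference values
day,p50_scr_mg_dl
1,0.7
2,0.876
3,0.943
4,0.944
5,0.908
6,0.854
7,0.791
8,0.729
9,0.671
10,0.618
11,0.571
12,0.531
13,0.498
14,0.469
15,0.446
16,0.427
17,0.412
18,0.399
19,0.389
20,0.381
21,0.374
22,0.369
23,0.365
24,0.362
25,0.359
26,0.357
27,0.356
28,0.354
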