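temperature_C,signal
25,0.4994093455809283
26,0.501555319448742
27,0.5019231196527495
28,0.501369892183994
29,0.5000044918529415
30,0.5011697787522394
31,0.50004221234752
32,0.5011279279485495
33,0.4999340465827289
34,0.5013892194606818
35,0.5003972472537026
36,0.5014905207510281
37,0.5026146710594303
38,0.5030325480996931
39,0.5058351110105039
40,0.5095881908674434
41,0.5159042360356093
42,0.5242080067657263
43,0.5358828081936947
44,0.5557069345526273
45,0.5795422931271718
46,0.6130834756825092
47,0.6501249792036773
48,0.6864863969598914
49,0.7199556010629381
50,0.7445823934430558
51,0.7655381500460788
52,0.7780029373633499
53,0.7854128046831675
54,0.7899213399467685
55,0.7933243438043293
56,0.7964085117486196
57,0.798248257788777
58,0.7994263609784327
59,0.7996473874326931
60,0.799232913031897
61,0.7999946339272751
62,0.7995988772832224
63,0.8010772157189752
64,0.7999532551445552
65,0.7995749246961722
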