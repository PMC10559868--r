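temperature_C,signal
25,0.5012406811922886
26,0.5009687965688112
27,0.5036055023098897
28,0.503464670898684
29,0.5064241365204556
30,0.5091676427455504
31,0.5153343178536062
32,0.5229704657113899
33,0.5354320321107084
34,0.5557222869869322
35,0.5796981918365576
36,0.6136778844568478
37,0.6487751139206959
38,0.6850673749216692
39,0.7189217037207545
40,0.7450977906475765
41,0.765495911755639
42,0.7773331429147741
43,0.7856692431176867
44,0.7918383334815264
45,0.7948404254152556
46,0.7983564641824834
47,0.7983138068996525
48,0.7978380895713737
49,0.7998163787676137
50,0.7996840643993529
51,0.7984132994731272
52,0.7980098269882215
53,0.7989481329766397
54,0.7992836425623105
55,0.7999555920241538
56,0.8007405637699109
57,0.7996412382932768
58,0.7995178789334181
59,0.7997490862069175
60,0.7994517935578923
61,0.79969857617269835
62,0.7997814982172486
63,0.7992228240434103
64,0.7992373150356353
65,0.8000900568521664
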