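ligand_total_M,signal
0,0.660119145115201
2e-5,0.642754481637237
2.9613525305595012e-5,0.6335639034916264
4.3848044051255805e-5,0.6248087518038217
6.492475810563541e-5,0.6096989569850759
9.613254835604366e-5,0.5906560941764384
1.4234118267165172e-4,0.5669434753427337
2.10761210753764e-4,0.5391479120582731
3.1206912240472166e-4,0.5094301312769122
4.62073342671353e-4,0.47988956337900063
6.841810313119501e-4,0.4513581450500399
0.0010130506142182261,0.4260797546817806
0.0015000000000000005,0.4055347144516086
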