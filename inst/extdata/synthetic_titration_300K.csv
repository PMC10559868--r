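ligand_total_M,signal
0,0.6594080363992275
2e-5,0.623137383986155
2.9613525305595012e-5,0.6091805991298104
4.3848044051255805e-5,0.5883529620089114
6.492475810563541e-5,0.5652698698605828
9.613254835604366e-5,0.5378151103697193
1.4234118267165172e-4,0.5081773955252816
2.10761210753764e-4,0.4775656759064526
3.1206912240472166e-4,0.45042606873415947
4.62073342671353e-4,0.4249804204758714
6.841810313119501e-4,0.40516740049933414
0.0010130506142182261,0.3897945824730848
0.0015000000000000005,0.37761432100173437
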