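-0.9350608191027171
1.0850599519661419
-0.53071890299248881
-0.7106618630030751
-0.0065394086710474772
-1.3816312527582586
0.63619229675360578
-0.99387373679234037
-0.15879541365332839
-0.27370408016064068
0.72471626379288656
-0.49056037300348415
-0.75201650795692532
-0.64531260909949117
1.3201014867185659
0.59628207583311466
 2.108542319380792
-1.2785226395771074
0.36928441648928273
0.42167820257313626
-2.1470296058238416
1.0044368428703581
0.47138064495855131
-1.4470775608541513
1.0411449755786175
0.72906021528153242
-1.2379657299972362
1.3251506425746284
-0.18527823242504615
0.48889422596044357
-0.94624792391216206
1.4279737132346895
0.66277630619168082
-0.027260749372241887
-0.26574918652742752
-0.71581341569697488
-0.48611599815427037
-0.0030508712073832956
0.48402558811994922
0.72380815617195782
0.70872651493973204
-0.0064665521107372149
0.10604856776109278
1.1092029774493846
-0.091642752636165642
-0.59030806452198681
-0.49607083239635757
-0.5985269760707066
-1.2513155080694562
-0.40795692169644648
1.1508302809113713
0.21030655604184587
0.79934336866985256
-0.87461697174541564
-0.28349563747691348
-0.47380636688472577
-0.53442685411054447
0.055360596638316578
0.036646132898702673
-0.10175429727882211
-1.7642931996874398
1.1038618506561906
-0.42419612251653122
0.32006479715601921
0.34074577150332208
0.94185347631513405
0.01558675370856932
1.0643289740380042
-0.56495708725467186
1.0588880828735814
-0.50031387727001764
1.2835849564832877
-0.53544621825226268
-1.9869805907733813
0.80469604850736187
-0.28856493123566201
-0.82282124043964389
-1.2733291538539226
-1.0065997887576223
1.6785875900687739
-0.40547676341686301
0.12725532221232766
-0.80038382468851976
0.14481353433379951
0.43753949692071742
0.69411702362026617
0.98915918594063701
-1.6921197396550671
0.015150954716593751
0.95445155016174477
-0.73535726566952575
-0.8275508963171494
0.53969119660770715
0.31153824335705671
0.95806274018924753
-1.0667980347956116
0.17132610291507586
0.52463613103422246
0.52023315324831176
-1.0003362882886153
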