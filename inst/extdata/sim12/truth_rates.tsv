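child_tips	duration_myr	rate
t3;t4;t5;t6;t7	1.802314052	0.005824975885
t1;t10;t11;t12;t2;t8;t9	0.4010731787	0.004290405081
t1	2.519846827	0.003750889167
t10;t11;t12;t2;t8;t9	1.422592614	0.003949579805
t10;t11;t12	0.9552904721	0.0039345809
t2;t8;t9	0.07952972808	0.003635157882
t8;t9	0.6752008804	0.003512478905
t2	1.017724485	0.003805126974
t8	0.3425236043	0.004271829435
t9	0.3425236043	0.003574002694
t11;t12	0.06519619985	0.00364901747
t10	0.1419637407	0.003855739228
t11	0.07676754082	0.003756580763
t12	0.07676754082	0.004089185724
t4;t5	0.4270110668	0.005286489076
t3;t6;t7	0.3754775275	0.005267102556
t3	0.7431284259	0.004921704374
t6;t7	0.3995120157	0.005078142477
t6	0.3436164102	0.005273778142
t7	0.3436164102	0.004999306246
t4	0.6915948866	0.005118824027
t5	0.6915948866	0.004307639719
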