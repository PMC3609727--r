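tips	age_myr
t1	0
t2	0
t3	0
t4	0
t5	0
t6	0
t7	0
t8	0
t9	0
t10	0
t11	0
t12	0
t1;t10;t11;t12;t2;t3;t4;t5;t6;t7;t8;t9	2.920920005
t1;t10;t11;t12;t2;t8;t9	2.519846827
t2;t8;t9	1.017724485
t10;t11;t12;t2;t8;t9	1.097254213
t3;t6;t7	0.7431284259
t3;t4;t5;t6;t7	1.118605953
t4;t5	0.6915948866
t6;t7	0.3436164102
t8;t9	0.3425236043
t10;t11;t12	0.1419637407
t11;t12	0.07676754082
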