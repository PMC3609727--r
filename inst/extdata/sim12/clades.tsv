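name	n_min	n_max_known	tips
cladeA	5	10	t3;t4;t5;t6;t7
cladeB	7	14	t1;t2;t8;t9;t10;t11;t12
all	12	NA	t1;t2;t3;t4;t5;t6;t7;t8;t9;t10;t11;t12
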