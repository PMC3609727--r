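(((t4:0.003540152522,t5:0.002979141603):0.00225738934,(t3:0.003657458424,(t6:0.001812156713,t7:0.001717843666):0.002028778937):0.001977678645):0.01049843589,(t1:0.009451666165,(((t11:0.0002883834671,t12:0.000313916732):0.0002379020722,t10:0.0005473751638):0.003758667646,((t8:0.001463202415,t9:0.001224180285):0.002371628849,t2:0.003872570889):0.0002891031179):0.005618643058):0.001720766404);
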