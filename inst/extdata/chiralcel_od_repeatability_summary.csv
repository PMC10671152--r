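quantity,n_injections,mean,sd
rt_ezetimibe,20,36.02,0.20
rs_crit1,20,1.99,0.02
rs_crit2,20,2.71,0.07
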