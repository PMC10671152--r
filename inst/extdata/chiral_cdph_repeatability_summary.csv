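quantity,n_injections,mean,sd
rt_ezetimibe,20,26.03,0.16
rs_crit,20,1.63,0.06
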