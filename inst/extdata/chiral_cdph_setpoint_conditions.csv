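setpoint,temp_c,flow_ml_min,ternary_fraction,time_min,organic_pct
1,5,0.5,1,0,60
1,5,0.5,1,50,100
1,5,0.5,1,55,100
2,5,0.5,1,0,50
2,5,0.5,1,30,100
2,5,0.5,1,42,100
3,5,0.7,1,0,50
3,5,0.7,1,30,100
3,5,0.7,1,40,100
4,5,0.5,0.5,0,50
4,5,0.5,0.5,40,100
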