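setpoint,temp_c,flow_ml_min,ternary_fraction,time_min,organic_pct
1,15,0.7,0,0,26
1,15,0.7,0,70,86
2,20,0.7,0,0,26
2,20,0.7,0,40,86
2,20,0.7,0,45,86
3,30,0.7,0,0,34
3,30,0.7,0,24,53
3,30,0.7,0,40,95
3,30,0.7,0,45,95
4,20,0.7,1,0,50
4,20,0.7,1,50,100
4,20,0.7,1,60,100
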