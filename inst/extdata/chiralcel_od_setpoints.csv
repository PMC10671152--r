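setpoint,analyte,predicted_rt,experimental_rt
1,ezetimibe diol,23.72,25.73
1,desfluoro ezetimibe,32.20,34.86
1,ezetimibe,33.97,36.16
1,THP compound,35.79,38.17
1,ezetimibe ketone,41.79,44.59
1,TBDMS ketone,56.38,58.33
1,benzylated ezetimibe,63.41,65.94
2,ezetimibe diol,20.19,20.12
2,desfluoro ezetimibe,25.72,25.48
2,ezetimibe,26.70,26.25
2,THP compound,27.80,27.33
2,ezetimibe ketone,31.80,31.40
2,TBDMS ketone,40.10,39.57
2,benzylated ezetimibe,44.31,43.62
3,ezetimibe diol,17.50,17.57
3,ezetimibe,25.70,27.81
3,THP compound,27.55,30.06
3,ezetimibe ketone,32.27,35.40
3,TBDMS ketone,39.38,41.58
3,benzylated ezetimibe,42.26,43.60
4,ezetimibe diol,27.29,25.00
4,ezetimibe,36.61,35.91
4,monofluoro ezetimibe,38.28,37.26
4,ezetimibe ketone,45.92,46.41
4,TBDMS ketone,50.29,52.44
4,benzylated ezetimibe,52.23,55.50
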