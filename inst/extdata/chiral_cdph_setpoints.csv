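setpoint,analyte,predicted_rt,experimental_rt
1,ezetimibe diol,22.22,20.48
1,THP compound,27.76,26.46
1,RRS ezetimibe,31.02,30.10
1,monofluoro ezetimibe,32.38,31.22
1,ezetimibe,33.85,33.16
1,ezetimibe ketone,41.13,40.78
1,TBDMS ketone,49.30,50.45
1,benzylated ezetimibe,50.83,52.08
2,ezetimibe diol,23.02,23.11
2,THP compound,26.19,26.59
2,RRS ezetimibe,28.07,28.51
2,ezetimibe,29.79,30.00
2,ezetimibe ketone,34.06,34.19
2,TBDMS ketone,38.73,37.85
2,benzylated ezetimibe,41.10,39.11
3,ezetimibe diol,19.05,18.32
3,THP compound,22.37,21.89
3,RRS ezetimibe,24.17,23.79
3,ezetimibe,25.74,25.20
3,ezetimibe ketone,29.70,29.63
3,TBDMS ketone,33.93,34.68
3,benzylated ezetimibe,35.15,35.34
4,ezetimibe diol,18.97,18.06
4,ezetimibe,23.96,23.60
4,ezetimibe ketone,28.55,28.35
4,TBDMS ketone,37.13,37.62
4,benzylated ezetimibe,34.76,35.07
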