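analyte,predicted_rt,exp_initial,exp_2y_inj1,exp_2y_inj20
ezetimibe diol,19.05,18.32,19.27,19.31
THP compound,22.37,21.89,22.72,22.81
RRS ezetimibe,24.17,23.79,24.52,24.61
ezetimibe,25.74,25.20,25.99,26.09
ezetimibe ketone,29.70,29.63,29.88,29.95
TBDMS ketone,33.93,34.68,34.27,34.36
benzylated ezetimibe,35.15,35.34,35.38,35.48
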