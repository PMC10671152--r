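analyte,predicted_rt,exp_initial,exp_2y_inj1,exp_2y_inj20
ezetimibe diol,23.72,25.73,25.57,25.65
desfluoro ezetimibe,32.20,34.86,34.78,34.87
ezetimibe,33.97,36.16,35.99,36.06
THP compound,35.79,38.17,37.91,37.98
ezetimibe ketone,41.79,44.59,44.55,44.61
TBDMS ketone,56.38,58.33,58.30,58.36
benzylated ezetimibe,63.41,65.94,65.75,65.81
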