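day,calibration_pct,pred_1param_pct,pred_4param_pct
3,23.6,20.9,21.9
5,11.1,15.9,18
7,18.5,23.8,25.2
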