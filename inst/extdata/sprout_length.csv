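day,observed_mean_um,observed_sd_um,predicted_mean_um,predicted_sd_um,error_pct
3,119.8,75.8,140.2,8.9,17.1
7,232.4,67.7,318.6,14.6,37.1
11,490.6,129.5,497.6,29.5,14.6
15,722.7,198.7,676.0,29.5,6.3
19,869.9,191,856.8,37.6,1.5
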