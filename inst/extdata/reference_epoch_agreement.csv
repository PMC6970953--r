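device,placement,n_subjects,accuracy_pct,accuracy_low,accuracy_high,sensitivity_pct,sensitivity_low,sensitivity_high,specificity_pct,specificity_low,specificity_high,pabak_published,pabak_low,pabak_high
ActiGraph GT3X+,hip,28,88.2,84.1,91.3,97.2,96.1,98.0,41.6,30.9,53.2,0.76,0.75,0.77
ActiGraph GT3X+,wrist,28,90.2,86.3,93.1,95.7,94.5,96.4,62.0,47.0,74.9,0.81,0.80,0.81
Actical,hip,28,86.7,82.7,90.0,99.5,92.2,99.6,21.1,15.3,28.3,0.74,0.73,0.74
Actical,wrist,27,86.0,76.2,92.2,98.0,97.3,98.6,45.7,34.2,57.3,0.79,0.65,0.66
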