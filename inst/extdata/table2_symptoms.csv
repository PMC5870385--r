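symptom,agreement_pct,kappa,p_value,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,prevalence_pct
fever,83.5,0.59,<0.01,90.4,67.1,86.8,74.6,70.5
cough,82.3,0.64,<0.01,91.5,71.0,79.3,87.4,54.9
diarrhoea,84.4,0.57,<0.01,86.1,84.0,54.4,96.5,18.1
vomiting,76.4,0.42,<0.01,67.2,79.3,51.3,88.2,24.5
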