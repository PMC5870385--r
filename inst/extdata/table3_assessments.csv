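assessment,triage,agreement_pct,kappa,p_value,sensitivity_pct,specificity_pct,ppv_pct,npv_pct,prevalence_pct
neurological_emergency,A,77.2,-0.01,0.71,0,77.5,0,99.5,0.4
severe_rti,A,84.0,0.30,<0.01,54.6,87.0,30.0,94.9,9.3
gi_severe_dehydration,A,93.3,0.08,0.09,16.7,95.2,8.3,97.8,2.5
inability_to_drink,A,n/a,n/a,n/a,n/a,n/a,n/a,n/a,n/a
severe_febrile_disease,A,n/a,n/a,n/a,n/a,n/a,n/a,n/a,n/a
febrile_disease,B,78.9,0.51,<0.01,83.2,68.6,86.3,63.2,70.5
moderate_rti,B,63.7,0.05,0.21,27.3,77.8,32.1,73.5,27.9
gi_some_dehydration,B,81.9,0.25,<0.01,66.7,82.9,20.8,97.4,6.3
dysentery,B,84.0,0.17,<0.01,71.4,84.3,12.2,99.0,3.0
mild_rti,C,62.5,-0.07,0.87,17.0,75.5,16.7,76.0,22.4
gi_no_dehydration,C,73.4,0.20,<0.01,27.4,89.7,48.6,77.7,26.2
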