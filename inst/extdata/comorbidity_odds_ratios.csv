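comorbidity,level,cholesterol,horizon,odds_ratio
hypertension,present,none,10,1.29
hypertension,present,none,15,1.38
angina,present,none,10,1.55
angina,present,none,15,1.62
angina,present,high_total,10,1.84
angina,present,high_total,15,2.08
angina,present,low_hdl,10,2.26
angina,present,low_hdl,15,2.72
angina,present,both,10,3.12
angina,present,both,15,4.09
congestive_heart_failure,present,none,10,3.82
congestive_heart_failure,present,none,15,3.67
heart_attack,present,none,10,1.55
heart_attack,present,none,15,1.62
heart_attack,present,high_total,10,1.84
heart_attack,present,high_total,15,2.08
heart_attack,present,low_hdl,10,2.26
heart_attack,present,low_hdl,15,2.72
heart_attack,present,both,10,3.12
heart_attack,present,both,15,4.09
aortic_stenosis,present,none,10,1.29
aortic_stenosis,present,none,15,1.38
aortic_stenosis,present,high_total,10,1.62
aortic_stenosis,present,high_total,15,1.76
aortic_stenosis,present,low_hdl,10,2.00
aortic_stenosis,present,low_hdl,15,2.27
aortic_stenosis,present,both,10,2.77
aortic_stenosis,present,both,15,3.67
atrial_fibrillation,present,none,10,1.29
atrial_fibrillation,present,none,15,1.38
asthma,mild,none,10,1.17
asthma,mild,none,15,1.17
asthma,moderate,none,10,2.00
asthma,moderate,none,15,2.27
asthma,severe,none,10,2.45
asthma,severe,none,15,2.85
abdominal_aortic_aneurysm,present,none,10,1.92
abdominal_aortic_aneurysm,present,none,15,1.99
peripheral_vascular_disease,present,none,10,1.62
peripheral_vascular_disease,present,none,15,1.76
peripheral_vascular_disease,present,high_total,10,2.00
peripheral_vascular_disease,present,high_total,15,2.27
peripheral_vascular_disease,present,low_hdl,10,2.36
peripheral_vascular_disease,present,low_hdl,15,2.85
peripheral_vascular_disease,present,both,10,3.25
peripheral_vascular_disease,present,both,15,4.60
deep_venous_thrombosis,present,none,10,1.84
deep_venous_thrombosis,present,none,15,1.99
deep_venous_thrombosis,present,high_total,10,2.17
deep_venous_thrombosis,present,high_total,15,2.60
deep_venous_thrombosis,present,low_hdl,10,2.56
deep_venous_thrombosis,present,low_hdl,15,3.30
deep_venous_thrombosis,present,both,10,3.52
deep_venous_thrombosis,present,both,15,4.89
pulmonary_embolus,present,none,10,1.00
pulmonary_embolus,present,none,15,1.00
pulmonary_embolus,present,high_total,10,1.29
pulmonary_embolus,present,high_total,15,1.38
pulmonary_embolus,present,low_hdl,10,1.62
pulmonary_embolus,present,low_hdl,15,1.76
pulmonary_embolus,present,both,10,2.36
pulmonary_embolus,present,both,15,2.85
smoking,current,none,10,2.00
smoking,current,none,15,2.00
smoking,former,none,10,1.50
smoking,former,none,15,1.50
diabetes,0-5,none,10,1.00
diabetes,0-5,none,15,1.00
diabetes,6-10,none,10,1.62
diabetes,6-10,none,15,1.76
diabetes,11-20,none,10,2.00
diabetes,11-20,none,15,2.27
diabetes,>20,none,10,2.36
diabetes,>20,none,15,2.85
stroke,hemorrhage,none,10,1.62
stroke,hemorrhage,none,15,1.76
stroke,infarction,none,10,2.36
stroke,infarction,none,15,2.85
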