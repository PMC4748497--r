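age,hypertension,angina,congestive_heart_failure,smoking,diabetes,high_total_cholesterol,low_hdl
65,0,0,0,current,none,0,0
65,0,1,0,never,none,0,0
72,1,0,1,former,6-10,1,0
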