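risk_group,age_band,horizon,risk
low,<65,15,0.05
low,65-74,15,0.07
low,75+,15,0.11
intermediate,<65,15,0.14
intermediate,65-74,15,0.17
intermediate,75+,15,0.22
high,<65,15,0.28
high,65-74,15,0.33
high,75+,15,0.42
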