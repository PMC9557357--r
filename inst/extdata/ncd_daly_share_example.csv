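country,ncd_daly_share_adults_20plus
China,0.84
Ghana,0.48
India,0.64
South Africa,0.30
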