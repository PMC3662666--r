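constant,value
target_factor_B,5.4558
intensity.benzene,1.00
intensity.hetero6,0.90
intensity.ring5,0.60
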