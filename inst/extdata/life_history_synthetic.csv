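# life-history parameters for the worked example (synthetic grayling parameterization)
species,linf_cm,k,t0,t_max,gsi
grayling,40,0.127,0,17,0.1676
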