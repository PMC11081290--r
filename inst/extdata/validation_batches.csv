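response,target,validation_mean,validation_sd,n
high_shear_visc,5.32,5.73,0.18,3
low_shear_visc,14608,14266.67,665.83,3
storage_modulus,530.7,559,52.6,3
yield_stress,44.98,47.73,1.29,3
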