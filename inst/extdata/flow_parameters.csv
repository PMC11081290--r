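run_id,consistency_Pa_s,flow_index,r_squared
DoE1,173.5,0.32,0.9975
DoE2,233.4,0.20,0.9996
DoE3,332.2,0.14,0.9976
DoE4,430.8,0.07,0.9989
DoE5,444.5,0.03,0.9995
DoE6,728.4,0.05,0.9998
DoE7,403.2,0.18,0.9996
DoE8,215.8,0.15,1
DoE9,372.8,0.18,0.9991
DoE10,188.2,0.12,0.9992
DoE11,244.6,0.24,0.9988
DoE12,783,0.12,0.9903
DoE13,406.1,0.17,0.9957
DoE14,177.2,0.06,0.9973
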