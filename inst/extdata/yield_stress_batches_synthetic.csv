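run_id,yield_stress_Pa
DoE1,38.5
DoE2,37.1
DoE3,35.0
DoE4,37.7
DoE5,39.8
DoE6,36.3
DoE7,52.0
DoE8,73.3
DoE9,51.2
DoE10,35.8
DoE11,70.3
DoE12,75.1
DoE13,74.0
DoE14,35.5
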