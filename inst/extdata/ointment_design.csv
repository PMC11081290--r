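run_id,drug_ratio,mixing_time,mixing_speed,petroleum,liquid_paraffin,method
DoE1,35,45,1800,85,10,B
DoE2,20,5,1800,77.5,10,A
DoE3,35,25,1050,77.5,7.5,B
DoE4,20,25,1800,70,5,B
DoE5,35,25,1050,77.5,7.5,A
DoE6,50,5,1050,70,10,B
DoE7,50,25,300,85,10,A
DoE8,20,5,300,85,7.5,B
DoE9,50,45,1800,70,7.5,A
DoE10,20,45,300,70,10,A
DoE11,20,45,1050,85,5,A
DoE12,50,5,1800,85,5,B
DoE13,50,45,300,77.5,5,B
DoE14,35,5,300,70,5,A
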