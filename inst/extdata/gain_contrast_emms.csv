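trait,benchmark,emm_high,emm_low
yield,elite_elite,1091.3,36.7
yield,elite_wild,1091.3,16.2
count,elite_elite,40.4,2.6
count,elite_wild,40.4,1.0
weight,elite_elite,41.7,12.7
weight,elite_wild,41.7,6.9
firmness,elite_elite,1.39,0.41
firmness,elite_wild,1.39,0.16
tss,elite_elite,15.2,5.5
tss,elite_wild,15.2,7.4
ta,elite_elite,1.16,0.57
ta,elite_wild,1.16,0.64
tss_ta,elite_elite,18.9,6.2
tss_ta,elite_wild,18.9,7.7
anthocyanin,elite_elite,241.8,47.8
anthocyanin,elite_wild,241.8,45.4
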