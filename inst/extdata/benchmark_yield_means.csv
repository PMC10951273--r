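group,cumulative_kg_ha,per_harvest_kg_ha
day_neutral,79921,3979
short_day,41208,2114
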