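predicted,spawning_redds,vegetation,underwater_rocks,aquatic_vegetation,anthropogenic_feature,sediment
unclassified,0,0,0,0,0,0
spawning_redds,1009,0,0,114,56,0
vegetation,0,929,160,0,0,241
underwater_rocks,0,0,943,0,0,42
aquatic_vegetation,2,0,0,619,0,85
anthropogenic_feature,0,84,3,0,988,0
sediment,0,0,117,340,0,701
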