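predicted,spawning_redds,vegetation,underwater_rocks,aquatic_vegetation,anthropogenic_feature,sediment
unclassified,0,1,0,0,0,0
spawning_redds,962,0,0,100,43,0
vegetation,0,925,30,0,0,132
underwater_rocks,0,5,920,0,0,0
aquatic_vegetation,49,0,0,973,0,0
anthropogenic_feature,0,78,0,0,1001,0
sediment,0,4,273,0,0,937
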