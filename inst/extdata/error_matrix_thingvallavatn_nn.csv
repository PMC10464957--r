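predicted,spawning_redds,vegetation,underwater_rocks,deep_water,shoreline,surface_rocks
unclassified,0,0,0,0,0,0
spawning_redds,931,2,23,82,9,0
vegetation,0,708,29,7,0,25
underwater_rocks,17,213,909,2,0,174
deep_water,62,0,16,910,0,0
shoreline,0,32,0,0,1006,21
surface_rocks,0,52,36,0,2,894
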