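predicted,spawning_redds,vegetation,underwater_rocks,deep_water,shoreline,surface_rocks
unclassified,0,1,0,0,0,0
spawning_redds,919,0,26,9,0,0
vegetation,0,867,39,0,0,70
underwater_rocks,15,92,924,26,0,116
deep_water,74,0,24,966,0,0
shoreline,2,20,0,0,1011,21
surface_rocks,0,27,0,0,6,907
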