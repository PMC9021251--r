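sample,geometry,zoneA_threshold_V_per_cm,zoneB_threshold_V_per_cm,zoneA_dsc,zoneB_dsc
S1,hexagonal,1230,760,0.71,0.74
S2,hexagonal,1150,800,0.65,0.70
S3,linear,1260,770,0.67,0.85
S4,linear,1260,890,0.75,0.87
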