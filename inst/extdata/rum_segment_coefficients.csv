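variable,estimate
grade_steep,-1.795
traffic_moderate,-1.027
traffic_heavy,-1.604
road_type_minor_arterial,-0.904
road_type_major_arterial,-2.178
continuity_continuous,1.325
segregation_exclusive,1.859
mean_exposure,-0.058
max_exposure,-0.034
travel_time,-0.050
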