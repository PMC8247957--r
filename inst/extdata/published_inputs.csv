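quantity,value
cti_trend_inside_c_per_yr,0.0098
cti_trend_outside_c_per_yr,0.0057
temp_trend_c_per_yr,0.04
cti_lat_gradient_c_per_deg,-0.31
temp_lat_gradient_c_per_deg,-0.38
temp_velocity_km_per_yr,11.4
horizon_yr,25
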