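age_class,nominal_age_y,height_cm,weight_kg,trunk_semi_axis_lat_cm,trunk_semi_axis_ap_cm,heart_offset_lat_cm,heart_offset_ap_cm,heart_offset_cc_cm
newborn,0,50.9,3.4,5.4,4.9,0,0,0
1y,1,74.4,9.2,8.8,6.5,0,0,0
5y,5,109.1,19.0,11.45,7.5,0,0,0
10y,10,139.8,32.4,13.9,8.4,0,0,0
15y,15,168.1,56.3,17.25,9.8,0,0,0
adult,20,178.6,73.2,20.0,10.0,0,0,0
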