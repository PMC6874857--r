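"threat","category","magnitude","distance_m","magnitude_rule","attribute","mag_min","mag_max","distance_rule"
"human_settlements","urban_area",0.65,10000,"fixed",,,,"fixed"
"human_settlements","village",0.35,3000,"fixed",,,,"fixed"
"mining","construction_material",0.6,5000,"fixed",,,,"fixed"
"mining","metal",0.4,5000,"fixed",,,,"fixed"
"mining","non_metal",0.1,5000,"fixed",,,,"fixed"
"agriculture","crops",0.6,5000,"fixed",,,,"fixed"
"agriculture","mosaic_pasture",0.4,5000,"fixed",,,,"fixed"
"hydroelectric","operating_large",0.375,30000,"fixed",,,,"plant_size"
"hydroelectric","operating_medium",0.225,30000,"fixed",,,,"plant_size"
"hydroelectric","operating_small",0.15,30000,"fixed",,,,"plant_size"
"hydroelectric","construction_large",0.125,30000,"fixed",,,,"plant_size"
"hydroelectric","construction_medium",0.075,30000,"fixed",,,,"plant_size"
"hydroelectric","construction_small",0.05,30000,"fixed",,,,"plant_size"
"thermoelectric","plant",1,2000,"fixed",,,,"fixed"
"oil","well_operating",0.28,1500,"fixed",,,,"fixed"
"oil","well_not_operating",0.07,1500,"fixed",,,,"fixed"
"oil","spill_recent_high",0.15,5000,"fixed",,,,"fixed"
"oil","spill_recent_low",0.09,5000,"fixed",,,,"fixed"
"oil","spill_old_high",0.075,5000,"fixed",,,,"fixed"
"oil","spill_old_low",0.015,5000,"fixed",,,,"fixed"
"oil","pool_no_treatment",0.2,5000,"fixed",,,,"fixed"
"oil","pool_recent_treated",0.0625,5000,"fixed",,,,"fixed"
"oil","pool_old_no_treatment",0.0125,5000,"fixed",,,,"fixed"
"oil","pipeline_risky",0.07,30,"fixed",,,,"fixed"
"oil","pipeline_out_of_risk",0.03,30,"fixed",,,,"fixed"
"aquaculture","farm",1,1000,"attribute","water_volume_m3",0.1,1,"fixed"
"water_withdrawals","withdrawal",1,1000,"attribute","water_volume_m3",0.1,1,"fixed"
"roads","primary",0.5,1000,"fixed",,,,"fixed"
"roads","secondary",0.3,1000,"fixed",,,,"fixed"
"roads","local",0.2,1000,"fixed",,,,"fixed"
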