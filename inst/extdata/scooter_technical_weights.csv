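"feature","absolute_weight","printed_relative_pct"
"Streamlined Design",1.8098,8.45
"Modular Component Design",4.0797,19.05
"Lightweight Vehicle Body",3.0141,14.07
"Multi-Directional Steering Wheels",2.2805,10.65
"Adjustable Safety Railings",1.7331,8.09
"Flexible Skin-Friendly Materials",0.2603,1.22
"Retractable Chassis",2.1747,10.15
"Anti-Slip Surface Texture Design",0.5969,2.79
"Warning Reflective Strip Design",0.4182,1.95
"Emergency Braking Device",0.4998,2.33
"Progressive Braking System",0.4998,2.33
"Foldable Walking Cane",2.5757,12.02
"Ergonomic Elastic Grip Design",1.4786,6.9
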