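"need","feature"
"A1","Streamlined Design"
"A1","Modular Component Design"
"A1","Lightweight Vehicle Body"
"A1","Multi-Directional Steering Wheels"
"A2","Adjustable Safety Railings"
"A2","Flexible Skin-Friendly Materials"
"A3","Adjustable Safety Railings"
"A3","Flexible Skin-Friendly Materials"
"A3","Retractable Chassis"
"M1","Multi-Directional Steering Wheels"
"M1","Anti-Slip Surface Texture Design"
"M1","Adjustable Safety Railings"
"M1","Retractable Chassis"
"M2","Warning Reflective Strip Design"
"M2","Emergency Braking Device"
"M3","Anti-Slip Surface Texture Design"
"M3","Flexible Skin-Friendly Materials"
"M4","Progressive Braking System"
"M4","Anti-Slip Surface Texture Design"
"O1","Retractable Chassis"
"O1","Foldable Walking Cane"
"O2","Multi-Directional Steering Wheels"
"O2","Retractable Chassis"
"O2","Foldable Walking Cane"
"O2","Lightweight Vehicle Body"
"O3","Retractable Chassis"
"O3","Adjustable Safety Railings"
"O3","Foldable Walking Cane"
"O4","Ergonomic Elastic Grip Design"
"O4","Adjustable Safety Railings"
"O4","Lightweight Vehicle Body"
"O4","Foldable Walking Cane"
"O5","Lightweight Vehicle Body"
"O5","Multi-Directional Steering Wheels"
"O6","Lightweight Vehicle Body"
"O6","Retractable Chassis"
"O6","Foldable Walking Cane"
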