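device,indication,fov_diameter_cm,fov_height_cm
accuitomo170,single tooth,4,4
accuitomo170,single tooth,6,6
accuitomo170,upper jaw,10,5
accuitomo170,upper jaw,8,8
accuitomo170,lower jaw,10,5
accuitomo170,lower jaw,8,8
accuitomo170,TMJ,10,10
accuitomo170,TMJ,14,10
accuitomo170,sinuses,10,10
accuitomo170,sinuses,14,10
accuitomo170,skull,14,10
accuitomo170,skull,17,12
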