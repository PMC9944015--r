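device,indication,age_years,cf_usv_per_mas
accuitomo170,single tooth,5,0.63
accuitomo170,single tooth,6,0.602
accuitomo170,single tooth,7,0.574
accuitomo170,single tooth,8,0.546
accuitomo170,single tooth,9,0.518
accuitomo170,single tooth,10,0.49
accuitomo170,single tooth,11,0.462
accuitomo170,single tooth,12,0.434
accuitomo170,single tooth,13,0.406
accuitomo170,single tooth,14,0.378
accuitomo170,single tooth,15,0.35
accuitomo170,upper jaw,5,0.99
accuitomo170,upper jaw,6,0.946
accuitomo170,upper jaw,7,0.902
accuitomo170,upper jaw,8,0.858
accuitomo170,upper jaw,9,0.814
accuitomo170,upper jaw,10,0.77
accuitomo170,upper jaw,11,0.726
accuitomo170,upper jaw,12,0.682
accuitomo170,upper jaw,13,0.638
accuitomo170,upper jaw,14,0.594
accuitomo170,upper jaw,15,0.55
accuitomo170,lower jaw,5,1.08
accuitomo170,lower jaw,6,1.032
accuitomo170,lower jaw,7,0.984
accuitomo170,lower jaw,8,0.936
accuitomo170,lower jaw,9,0.888
accuitomo170,lower jaw,10,0.84
accuitomo170,lower jaw,11,0.792
accuitomo170,lower jaw,12,0.744
accuitomo170,lower jaw,13,0.696
accuitomo170,lower jaw,14,0.648
accuitomo170,lower jaw,15,0.6
accuitomo170,TMJ,5,1.26
accuitomo170,TMJ,6,1.204
accuitomo170,TMJ,7,1.148
accuitomo170,TMJ,8,1.092
accuitomo170,TMJ,9,1.036
accuitomo170,TMJ,10,0.98
accuitomo170,TMJ,11,0.924
accuitomo170,TMJ,12,0.868
accuitomo170,TMJ,13,0.812
accuitomo170,TMJ,14,0.756
accuitomo170,TMJ,15,0.7
accuitomo170,sinuses,5,1.62
accuitomo170,sinuses,6,1.548
accuitomo170,sinuses,7,1.476
accuitomo170,sinuses,8,1.404
accuitomo170,sinuses,9,1.332
accuitomo170,sinuses,10,1.26
accuitomo170,sinuses,11,1.188
accuitomo170,sinuses,12,1.116
accuitomo170,sinuses,13,1.044
accuitomo170,sinuses,14,0.972
accuitomo170,sinuses,15,0.9
accuitomo170,skull,5,2.7
accuitomo170,skull,6,2.58
accuitomo170,skull,7,2.46
accuitomo170,skull,8,2.34
accuitomo170,skull,9,2.22
accuitomo170,skull,10,2.1
accuitomo170,skull,11,1.98
accuitomo170,skull,12,1.86
accuitomo170,skull,13,1.74
accuitomo170,skull,14,1.62
accuitomo170,skull,15,1.5
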