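extract,is_control,KP_zone,KP_sd,PA_zone,PA_sd,EC_zone,EC_sd
Coprinopsis cinerea,FALSE,,,,,,
Penicillium spinulosum,FALSE,,,,,,
Aspergillus flavus,FALSE,11.0,0.76,,,,
Aspergillus sp.,FALSE,,,12.15,0.28,,
Aspergillus peyronelii,FALSE,,,,,,
Aspergillus niger,FALSE,16.0,0.5,,,,
Aspergillus tubingensis,FALSE,14.5,0.57,11.0,0.12,,
Chaetomium globosum,FALSE,14.6,0.57,,,,
Aspergillus terreus,FALSE,16.8,0.50,11.00,1.0,,
P. formosus,FALSE,,,,,,
Control,TRUE,22.0,0.50,20.0,0.50,18.0,0.57
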