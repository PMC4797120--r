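extract,KP,PA
Aspergillus flavus,2.50,
Aspergillus sp.,,2.50
Aspergillus niger,0.62,
Aspergillus tubingensis,1.25,2.50
Chaetomium globosum,1.25,
Aspergillus terreus,0.62,2.50
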