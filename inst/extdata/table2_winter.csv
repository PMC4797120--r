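species,winter_site1_leaf,winter_site1_stem,winter_site1_petiole,winter_site2_leaf,winter_site2_stem,winter_site2_petiole,winter_site3_leaf,winter_site3_stem,winter_site3_petiole,winter_site4_leaf,winter_site4_stem,winter_site4_petiole,winter_site5_leaf,winter_site5_stem,winter_site5_petiole,winter_site6_leaf,winter_site6_stem,winter_site6_petiole
JP44MY2,1.4,,,,,,0.74,0.74,,2.2,2.2,0.74,6.6,,,3.7,2.9,
JP44MY3,5.1,13.3,,,7.4,,5.9,10.3,0.74,5.9,6.6,0.74,,7.4,,2.2,1.4,
JP44MY4,0.74,0.74,,,,,,,,7.4,1.4,1.4,2.9,1.4,0.74,,0.74,
JP44MY5,0.74,,,,,,,,,,,,0.74,,0.74,,,
JP44MY6,2.9,0.74,2.2,2.2,0.74,,7.4,1.4,,11.1,1.4,1.4,1.4,,,2.9,,
JP44MY8,2.2,2.9,2.2,39.2,8.1,13.3,10.3,4.4,0.74,2.9,2.9,0.74,8.1,2.2,0.74,6.6,1.4,0.74
JP44MY9,,,,,,,,,,,,,,,,,,
JP44MY10,1.4,,,,,,,,,,,,0.74,,,,,
JP44MY12,2.2,,2.2,5.1,1.4,2.2,2.9,0.74,,,,,,,,,,
JP44MY13,1.4,,,0.74,,,,,,2.9,,,0.74,,,,2.9,
JP44MY14,8.8,2.2,2.2,,0.74,,1.4,,13.3,3.7,0.74,,24.4,0.74,,6.6,4.4,0.74
JP44MY16,15.5,20,5.9,45.9,29.6,5.9,59.2,14.8,,,1.4,0.74,8.8,4.4,1.4,9.6,,0.74
JP44MY18,3.7,,,,,,,,,12.5,1.4,,4.4,0.74,,,,2.2
JP44MY22,,,,,,,,,,1.4,0.74,10.3,,,,,,
JP44MY23,5.9,2.9,,5.1,,,7.4,2.2,,49.6,13.3,,21.4,5.1,1.4,40.7,14.0,2.9
JP44MY24,4.4,4.4,,1.4,,,1.4,2.9,,,2.9,,1.4,,0.74,,0.74,
JP44MY25,,,,,,,,,,,,,,,,,,
JP44MY26,,,,,,,,,,,,,,,,,,
JP44MY27,,,,,,,,,,,,,,,,,,
JP44MY28,,,,,,,,,,,,,1.4,1.4,0.74,,,
JP44MY35,,,,,,,,,,,,,,,,,,
JP44MY41,2.2,4.4,6.6,,,1.4,8.8,4.4,,,,,,,,2.9,0.74,
JP44MY42,,,,,,,,,,,,,,,,,,
JP44MY43,,,,,,,,,,,,,,,,,,
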