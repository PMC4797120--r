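species,summer_site1_leaf,summer_site1_stem,summer_site1_petiole,summer_site2_leaf,summer_site2_stem,summer_site2_petiole,summer_site3_leaf,summer_site3_stem,summer_site3_petiole,summer_site4_leaf,summer_site4_stem,summer_site4_petiole,summer_site5_leaf,summer_site5_stem,summer_site5_petiole,summer_site6_leaf,summer_site6_stem,summer_site6_petiole
JP44MY2,,,,,,,,,,,,,0.74,,,,,
JP44MY3,,0.74,,,2.2,,,5.1,,,0.74,,,4.4,,,0.74,
JP44MY4,7.4,,,,,,2.2,,,,,,,,,,,
JP44MY5,,,,,0.74,,,,,0.74,,,,,,,,
JP44MY6,1.4,,0.74,2.2,,,2.9,1.4,,1.4,0.74,,0.74,0.74,,0.74,1.4,
JP44MY8,2.2,,0.74,0.74,1.4,,1.4,0.74,,2.2,0.74,,,,,2.2,,
JP44MY9,,,,0.74,0.74,,,,,,,,,,,,,
JP44MY10,0.74,0.74,,0.74,,,2.2,1.4,,2.2,0.74,,,,,1.4,0.74,
JP44MY12,,3.7,,2.2,,,4.4,2.2,0.74,,1.4,,0.74,,,0.74,,
JP44MY13,,,0.74,,,,,,,,,,,,,,,
JP44MY14,4.4,2.2,,5.1,3.7,,11.8,4.4,,,0.74,0.74,0.74,0.74,,1.4,,
JP44MY16,5.1,,,10.3,1.4,0.74,8.1,2.2,,,6.6,0.74,7.4,1.4,2.2,12.5,,2.2
JP44MY18,2.9,0.74,,3.7,0.74,,1.4,1.4,,2.2,0.74,,1.4,,,8.8,1.4,1.4
JP44MY22,1.4,0.74,0.74,0.74,2.9,1.4,2.9,2.2,,11.8,2.9,0.74,,,,0.74,,
JP44MY23,18.5,5.1,8.1,13.3,2.9,,46.6,21.4,8.1,5.9,,,1.4,,,3.7,1.4,0.74
JP44MY24,,,,1.4,,,,,,,,,,0.74,,,,
JP44MY25,,,,1.4,,,1.4,,,2.2,,,,,,,,
JP44MY26,0.74,,,,,,,,,,,,0.74,,,,,
JP44MY27,,,,,,,,,,,,,,,,,,
JP44MY28,,,,,,,,,,,,,,,,,,
JP44MY35,0.74,,0.74,,0.74,,,,,,,,,0.74,,,,
JP44MY41,1.4,,,,,,0.74,,,,,,2.2,,,,,
JP44MY42,1.4,,,0.74,,,,,,2.2,,,,,,0.74,,
JP44MY43,,,,,,,,,,,,,0.74,,,,,
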