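species,rainy_site1_leaf,rainy_site1_stem,rainy_site1_petiole,rainy_site2_leaf,rainy_site2_stem,rainy_site2_petiole,rainy_site3_leaf,rainy_site3_stem,rainy_site3_petiole,rainy_site4_leaf,rainy_site4_stem,rainy_site4_petiole,rainy_site5_leaf,rainy_site5_stem,rainy_site5_petiole,rainy_site6_leaf,rainy_site6_stem,rainy_site6_petiole
JP44MY2,1.4,,,,,,0.74,,0.74,,0.74,,3.7,,1.4,3.7,,
JP44MY3,,7.4,,3.7,8.1,1.4,2.2,5.9,,,,,2.2,2.9,0.74,,11.1,2.2
JP44MY4,,,,2.2,0.74,,0.74,2.2,,,,,1.4,,,1.4,1.4,
JP44MY5,0.74,,,1.2,,,2.2,,,,,,1.4,9.6,0.74,,,
JP44MY6,0.74,2.2,,2.2,0.74,0.74,1.4,,,0.74,,0.74,1.4,,,3.7,5.1,
JP44MY8,,,1.4,1.4,,,2.2,0.74,,,,0.74,3.7,,,1.4,1.4,
JP44MY9,1.4,,,,,,0.74,,,,,,0.74,,,,,
JP44MY10,1.4,1.4,,,,0.74,0.74,,,,,,1.4,,,,,
JP44MY12,2.2,2.9,,3.7,1.4,1.4,2.2,2.2,,,,,1.4,1.4,,1.4,0.74,
JP44MY13,,,1.4,1.4,,,2.9,,,1.4,0.74,,1.4,,,,,
JP44MY14,9.6,4.4,2.2,5.1,1.4,,28.8,0.74,,8.1,,,,,,6.6,2.2,0.74
JP44MY16,2.2,4.4,3.7,3.7,1.4,0.74,8.8,12.5,7.4,11.1,0.74,,0.74,0.74,0.74,7.4,,
JP44MY18,3.7,3.7,1.4,4.4,1.4,1.4,2.2,1.4,2.2,3.7,2.2,2.2,7.4,1.4,,5.9,1.4,
JP44MY22,1.4,,,0.74,2.2,,,,,14.8,,3.7,3.7,1.4,,2.5,3.7,2.2
JP44MY23,5.1,,0.74,10.3,3.7,3.7,,,,9.6,0.74,0.74,1.4,,0.74,0.74,2.2,
JP44MY24,,0.74,,2.2,,,,,,0.74,,,,,,,,
JP44MY25,,,,1.4,,,,,,1.4,2.9,,,,2.2,1.4,2.2,
JP44MY26,,,,,,,,,,,,0.74,,,,,,
JP44MY27,1.4,0.74,1.4,0.74,,0.74,,,,,0.74,,,,,,,
JP44MY28,,,,,,,,,,,0.74,,1.4,2.9,,,,
JP44MY35,0.74,,,,1.4,,,,,,,,0.74,,,,0.74,
JP44MY41,,,,0.74,,,,,,,2.9,,2.2,,,,,
JP44MY42,2.9,,0.74,,,,,,,,,,1.4,,,,,
JP44MY43,,,,0.74,,,,,,,,,,,,1.4,,
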