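species,n_mac_present,n_cont_present,n_mac_rcp45,pct_mac_rcp45,n_cont_rcp45,pct_cont_rcp45,n_mac_rcp85,pct_mac_rcp85,n_cont_rcp85,pct_cont_rcp85
Alophosia azorica,2698,766,1473,54.6,945,123.4,451,16.7,0,0
Andoa berthelotiana,3706,763,2077,56,580,76,879,23.7,0,0
Bazzania azorica,2066,1681,572,27.7,13,0.8,522,25.3,0,0
Breutelia azorica,2093,2134,856,40.9,170,8,428,20.4,1,0
Bryoxyphium madeirense,1157,321,349,30.2,1046,325.9,0,0,0,0
Calypogeia azorica,2353,2283,943,40.1,252,11,469,19.9,0,0
Cheilolejeunea cedercreutzii,694,189,198,28.5,0,0,161,23.2,0,0
Cololejeunea schaeferi,2406,358,672,27.9,1033,288.5,14,0.6,107,29.9
Cryptoleptodon longisetus,3395,809,1465,43.2,1799,222.4,336,9.9,361,44.6
Echinodium renauldii,2783,0,1046,37.6,0,NA,651,23.4,0,NA
Echinodium setigerum,749,672,304,40.6,2740,407.7,0,0,0,0
Echinodium spinosum,1034,536,303,29.3,692,129.1,0,0,0,0
Exsertotheca intermedia,8193,7905,2086,25.5,2207,27.9,0,0,0,0
Fissidens coacervatus,3991,3724,2202,55.2,2880,77.3,658,16.5,985,26.5
Fissidens nobreganus,1089,2473,474,43.5,429,17.3,1,0.1,0,0
Fissidens sublineaefolius,1344,4518,512,38.1,1025,22.7,0,0,0,0
Frullania polysticta,5073,9522,2283,45,2438,25.6,890,17.5,789,8.3
Grimmia curviseta,679,251,61,9,0,0,9,1.3,0,0
Hedenasiastrum percurrens,706,2133,235,33.3,21,1,8,1.1,0,0
Heteroscyphus denticulatus,6682,4470,1050,15.7,2747,61.5,369,5.5,461,10.3
Homalothecium mandonii,6288,6316,4191,66.7,3397,53.8,2526,40.2,852,13.5
Isothecium prolixum,2337,691,842,36,0,0,454,19.4,12,1.7
Leptoscyphus azoricus,802,276,171,21.3,0,0,122,15.2,0,0
Leucodon canariensis,4836,7661,1314,27.2,1513,19.7,451,9.3,357,4.7
Leucodon treleasei,1768,0,2644,149.5,0,NA,830,46.9,0,NA
Pelekium atlanticum,3377,3949,1360,40.3,1049,26.6,248,7.3,333,8.4
Plagiochila maderensis,3079,3465,1455,47.3,1537,44.4,252,8.2,313,9
Porella inaequalis,1368,6591,950,69.4,6027,91.4,733,53.6,3849,58.4
Radula wichurae,3506,64,2239,63.9,555,867.2,688,19.6,0,0
Rhynchostegiella bourgaeana,2568,91,241,9.4,0,0,21,0.8,4,4.4
Rhynchostegiella macilenta,3435,1968,1723,50.2,2199,111.7,757,22,986,50.1
Rhynchostegiella trichophylla,3445,260,905,26.3,140,53.8,201,5.8,375,144.2
Riccia atlantica,174,0,2,1.1,0,NA,0,0,0,NA
Telaranea azorica,796,152,309,38.8,0,0,162,20.4,0,0
Tortella limbata,2997,2789,282,9.4,721,25.9,276,9.2,174,6.2
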