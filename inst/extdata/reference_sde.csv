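year,month,areaKm2,centroidX,centroidY,rotationDeg
2008,January,578675,694751.22,1057483.83,101.28
2008,May,599409,696320.09,1048051.87,99.83
2008,August,600534,710984.51,1041396.29,99.47
2008,October,600450,713028.55,1039774.32,99.11
2018,January,500315,806753.97,996614.78,89.37
2018,May,500475,805644.60,996091.99,88.12
2018,August,504424,807421.15,994493.52,88.15
2018,October,501910,806805.26,995034.55,87.48
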