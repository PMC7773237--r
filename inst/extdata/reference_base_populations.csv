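district,basePopulation,agents10pct
Awdal,28510,2851
Woqooyi Galbeed,43740,4374
Togdheer,24280,2428
Sool,28980,2898
Sanaag,47760,4776
Bari,19110,1911
Nugaal,33370,3337
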