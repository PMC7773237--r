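district,jan2008,may2008,aug2008,oct2008,jan2018,may2018,aug2018,oct2018,totalDifference
Bari,2348,2485,2425,2402,1561,1549,1518,1516,-832
Nugaal,2670,2554,2526,2535,2564,2570,2563,2556,-114
Sanaag,4633,4068,3741,3581,1778,1783,1761,1762,-2871
Sool,3392,4172,4267,4346,2514,2408,2264,2149,-1243
Togdheer,3154,3754,3779,3777,2381,2431,2470,2568,-586
Woqooyi Galbeed,3534,2888,2086,2064,94,99,90,89,-3445
Awdal,2810,2483,2014,1852,150,141,137,133,-2677
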