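# synthetic stand-in for the experimental free-Gbg dataset
# generated by generateGproteinData(seed = 20181), noise_sd = sqrt(1.3e-4)
L_nM,T_s,mean,sd
1000,10,0.42964064152541204,0.011401754250991379
1000,30,0.45510435205739919,0.011401754250991379
1000,60,0.48633423856350977,0.011401754250991379
1000,120,0.4667668793398248,0.011401754250991379
1000,210,0.46843335250307383,0.011401754250991379
1000,300,0.46023943857791882,0.011401754250991379
1000,450,0.46971178815894038,0.011401754250991379
1000,600,0.48326975206880102,0.011401754250991379
1,60,0.080295577837992599,0.011401754250991379
2,60,0.11231516974237962,0.011401754250991379
5,60,0.24764719457408796,0.011401754250991379
10,60,0.31970466806797609,0.011401754250991379
20,60,0.39472077617500656,0.011401754250991379
50,60,0.46858034737676829,0.011401754250991379
100,60,0.46110048624211292,0.011401754250991379
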