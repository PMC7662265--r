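residue_number,residue_code,nucleus,shift_ppm
391,T,HA,4.37287247161341
391,T,HN,8.13803228317778
391,T,CA,61.7305707489565
392,V,HA,4.11587707048863
392,V,HN,8.0202932665888
392,V,CA,62.1052720054772
393,N,HA,4.74748139340291
393,N,HN,8.39883044774113
393,N,CA,53.1152657626282
394,P,HA,4.20009978107329
394,P,CA,65.2576986230329
395,I,HA,3.95536751783131
395,I,HN,8.0228145192599
395,I,CA,63.0544020540138
396,I,HA,3.9471606706681
396,I,HN,8.00467680511322
396,I,CA,62.9326199276915
397,Y,HA,4.30512671700463
397,Y,HN,8.11995177577732
397,Y,CA,59.92081641495
398,A,HA,4.08659750359624
398,A,HN,8.24705341830906
398,A,CA,54.5525964720812
399,L,HA,4.08432003783407
399,L,HN,8.17272916864255
399,L,CA,57.0404192771236
400,R,HA,4.1057227989574
400,R,HN,8.23591745052463
400,R,CA,57.8236947404229
401,S,HA,4.22543936044888
401,S,HN,8.30129148977431
401,S,CA,60.2938710553084
402,K,HA,4.07930652877769
402,K,HN,8.28921533232028
402,K,CA,58.0799509540658
403,D,HA,4.63437874123715
403,D,HN,8.34997513444755
403,D,CA,54.0894869941187
404,L,HA,4.19427712169225
404,L,HN,8.16314994904888
404,L,CA,56.3688550534507
405,R,HA,4.18870682921314
405,R,HN,8.22714567248471
405,R,CA,57.0158447327391
406,H,HA,4.58178987568551
406,H,HN,8.41598473386905
406,H,CA,56.2820517580923
407,A,HA,4.18161190027089
407,A,HN,8.24100525455629
407,A,CA,53.740107199552
408,F,HA,4.47307257651433
408,F,HN,8.29992331895287
408,F,CA,58.8837153006546
409,R,HA,4.35707162545138
409,R,HN,8.23723740262528
409,R,CA,56.0481036048708
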