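taxonID,parentNameUsageID,scientificName,taxonRank,taxonomicStatus,acceptedNameUsageID
1,,Animalia,kingdom,accepted,
2,1,Insecta,class,accepted,
3,2,Curculionidae,family,accepted,
4,3,Exemplarius,genus,accepted,
5,4,Exemplarius alpha,species,accepted,
6,4,Exemplarius beta,species,accepted,
7,4,Exemplarius gamma,species,accepted,
8,4,Exemplarius delta,species,accepted,
9,4,Exemplarius epsilon,species,accepted,
10,4,Exemplarius innocuus,species,accepted,
11,4,Exemplarius cinereus,species,accepted,
12,4,Exemplarius eta,species,accepted,
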