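taxonID,parentNameUsageID,scientificName,taxonRank,taxonomicStatus,acceptedNameUsageID
1,,Animalia,kingdom,accepted,
2,1,Insecta,class,accepted,
3,2,Coleoptera,order,accepted,
4,3,Curculionidae,family,accepted,
5,4,Exemplarius,genus,accepted,
6,5,Exemplarius alpha,species,accepted,
7,5,Exemplarius beta,species,accepted,
8,5,Exemplarius gamma,species,accepted,
9,5,Exemplarius delta,species,accepted,
10,5,Exemplarius epsilon,species,accepted,
11,5,Exemplarius microps,species,accepted,
12,5,Exemplarius theta,species,accepted,
13,5,Exemplarius iota,species,accepted,
14,5,Exemplarius kappa,species,accepted,
15,5,Exemplarius lambda,species,accepted,
16,5,Exemplarius mu,species,accepted,
17,5,Exemplarius nu,species,accepted,
18,5,Exemplarius xi,species,accepted,
19,5,Exemplarius omicron,species,accepted,
20,5,Exemplarius pi,species,accepted,
21,5,Exemplarius rho,species,accepted,
22,,Exemplarius innocuus,species,synonym,11
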