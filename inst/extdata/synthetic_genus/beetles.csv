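taxonID,parentNameUsageID,scientificName,taxonRank,taxonomicStatus,acceptedNameUsageID
1,,Curculionidae,family,accepted,
2,1,Exemplarius,genus,accepted,
3,2,Exemplarius alpha,species,accepted,
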