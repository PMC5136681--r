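{
  "comment": "Hand-authored synthetic miniature of a species-API store; no real aggregator data.",
  "datasets": {
    "ds-a": "Demo Checklist A",
    "ds-b": "Demo Checklist B",
    "ds-c": "Demo Aggregator C"
  },
  "usages": [
    {"key": "a1", "literal": "Animalia", "rank": "kingdom", "status": "accepted", "datasetKey": "ds-a"},
    {"key": "a2", "literal": "Arthropoda", "rank": "phylum", "status": "accepted", "parentKey": "a1", "datasetKey": "ds-a"},
    {"key": "a3", "literal": "Insecta", "rank": "class", "status": "accepted", "parentKey": "a2", "datasetKey": "ds-a"},
    {"key": "a4", "literal": "Nodea", "rank": "unranked", "status": "accepted", "parentKey": "a3", "datasetKey": "ds-a"},
    {"key": "a5", "literal": "Familidae", "rank": "family", "status": "accepted", "parentKey": "a4", "datasetKey": "ds-a"},
    {"key": "x1", "literal": "Xenus", "rank": "genus", "status": "accepted", "parentKey": "a5", "datasetKey": "ds-a"},
    {"key": "xm1", "literal": "Xenus minor", "rank": "species", "status": "accepted", "parentKey": "x1", "datasetKey": "ds-a"},
    {"key": "xj1", "literal": "Xenus major", "rank": "species", "status": "accepted", "parentKey": "x1", "datasetKey": "ds-a"},
    {"key": "x2", "literal": "Xenus", "rank": "genus", "status": "accepted", "datasetKey": "ds-b"},
    {"key": "x3", "literal": "Xenus", "rank": "genus", "status": "accepted", "datasetKey": "ds-c"},
    {"key": "x4", "literal": "Xenus", "rank": "unranked", "status": "accepted", "datasetKey": "ds-b", "denormalized": true},
    {"key": "x5", "literal": "Xenus", "rank": "unranked", "status": "accepted", "datasetKey": "ds-c"},
    {"key": "x6", "literal": "Xenus", "rank": "species", "status": "accepted", "datasetKey": "ds-a"},
    {"key": "al1", "literal": "Alphus", "rank": "genus", "status": "accepted", "parentKey": "a5", "datasetKey": "ds-a"},
    {"key": "al2", "literal": "Alphus", "rank": "genus", "status": "doubtful", "datasetKey": "ds-b"},
    {"key": "pa1", "literal": "Parella", "rank": "genus", "status": "accepted", "datasetKey": "ds-a", "basionym": "Parbas"},
    {"key": "pv1", "literal": "Parvex", "rank": "genus", "status": "synonym", "acceptedKey": "pa1", "datasetKey": "ds-a"},
    {"key": "pv2", "literal": "Parvex", "rank": "genus", "status": "accepted", "datasetKey": "ds-b"},
    {"key": "pa2", "literal": "Parella", "rank": "genus", "status": "synonym", "acceptedKey": "pv2", "datasetKey": "ds-b"},
    {"key": "pb1", "literal": "Parbas", "rank": "genus", "status": "accepted", "datasetKey": "ds-b"},
    {"key": "ca", "literal": "Chaina", "rank": "genus", "status": "accepted", "datasetKey": "ds-a"},
    {"key": "cb1", "literal": "Chainb", "rank": "genus", "status": "synonym", "acceptedKey": "ca", "datasetKey": "ds-a"},
    {"key": "cb2", "literal": "Chainb", "rank": "genus", "status": "accepted", "datasetKey": "ds-b"},
    {"key": "cc1", "literal": "Chainc", "rank": "genus", "status": "synonym", "acceptedKey": "cb2", "datasetKey": "ds-b"}
  ],
  "vernaculars": [
    {"key": "x1", "name": "demo beetle", "language": "en"},
    {"key": "al1", "name": "demo beetle", "language": "de"}
  ]
}
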