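genus	domain	evidence
Pseudomonas	bacteria	alkane and aromatic degradation, alk/nah pathways
Marinomonas	bacteria	aromatic hydrocarbon degradation in cold seawater
Oleispira	bacteria	obligate alkane degrader, psychrophilic
Cycloclasticus	bacteria	obligate PAH degrader, marine
Paraperlucidibaca	bacteria	aliphatic and aromatic degradation, biostimulated seawater
Colwellia	bacteria	several hydrocarbon classes, psychrophilic marine
Neptunomonas	bacteria	naphthalene-degrading marine genus
Paraglaciecola	bacteria	hydrocarbon degradation genes in polar MAGs
Glaciecola	bacteria	hydrocarbonoclastic in cold seawater enrichments
Marinobacter	bacteria	alkane degradation, ubiquitous marine
Alcanivorax	bacteria	obligate alkane degrader
Thalassolituus	bacteria	obligate alkane degrader
Pseudoalteromonas	bacteria	aromatic compound degradation
Shewanella	bacteria	hydrocarbon degradation genes
Alteromonas	bacteria	aromatic degradation in seawater
Halomonas	bacteria	alkane degradation, halotolerant
Idiomarina	bacteria	hydrocarbon-degrading isolates
Hyphomonas	bacteria	alkane degradation-related marine genus
Parvibaculum	bacteria	alkane and surfactant degradation
Sulfitobacter	bacteria	aromatic compound degradation, marine
Loktanella	bacteria	hydrocarbon degradation in polar waters
Sphingorhabdus	bacteria	aromatic degradation, sphingomonad pathways
Sneathiella	bacteria	hydrocarbon-associated marine isolates
Pacificibacter	bacteria	oil-enrichment associated genus
Ulvibacter	bacteria	hydrocarbon degradation genes in MAGs
Aequorivita	bacteria	oil-amended microcosm bloomer with HDGs
Lacinutrix	bacteria	hydrocarbon-degrading polar isolates
Dietzia	bacteria	alkane-degrading actinobacterium
Polaribacter	bacteria	hydrocarbon degradation genes in polar waters
Maribacter	bacteria	hydrocarbon-degrading species reported
Winogradskyella	bacteria	oil-enrichment associated flavobacterium
Methanosarcina	archaea	methanogenic alkane-associated consortia
Methanococcoides	archaea	methylotrophic methanogen in oil-impacted sediment
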