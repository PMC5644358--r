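Package: microassembly
Title: Community Assembly Analysis for Microbial Metacommunities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect the processes structuring microbial (and
    microeukaryotic) metacommunities from OTU count tables: rarefaction and
    alpha diversity, classification of OTUs into abundant/rare categories with
    MultiCoLA cutoff-robustness profiling, Bray-Curtis beta diversity with NMDS
    and ANOSIM, Mantel and partial Mantel distance-decay statistics, PCNM
    spatial eigenfunctions with RDA-based variation partitioning of
    environmental versus spatial effects, and least-squares fitting of the
    Sloan neutral community model. A synthetic metacommunity generator with
    known neutral or niche structure provides a ground-truth test bed for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
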