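Package: vectorscan
Title: Spatial Population Genomics of Anopheles Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Spatially explicit population-genomics analyses for densely
    sampled Anopheles gambiae s.l. collections: KING-robust kinship
    estimation with inversion-region masking, pedigree identity-by-descent
    simulation under genetic maps, Hudson Fst and isolation-by-distance
    inference (Rousset regression, Mantel and partial Mantel tests,
    doubleton sharing), Garud H12/H1X haplotype-homozygosity selection
    scans, diplotype hierarchical clustering, and copy-number inference
    from windowed coverage with a 13-state hidden Markov model. Includes a
    synthetic-data generator that emulates the statistical structure of a
    micro-spatial mosquito study (grid plus close-pair sampling, spatial
    allele-frequency autocorrelation, polymorphic inversions, nuclear
    families, planted selective sweeps and gene amplifications) so every
    stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
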