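Package: rotascreen
Title: Simulation and Analysis of ENU Mutagenesis Rotarod Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for forward-genetics motor screens in the mouse. Simulates
    ENU mutagenesis pedigrees (G1 x G2 backcrosses with Mendelian segregation,
    recessive lethality, planted behavioral alleles) together with weekly
    batches of accelerating-rotarod trial series; normalizes fall latencies
    against concurrent wild-type controls (weekly scaling factors, Z- and
    T-scores); extracts per-mouse learning-curve features and separates
    learning from non-learning mice by PCA plus density-based clustering;
    detects lethal alleles from distortion of expected Mendelian ratios;
    scans genotype-phenotype associations under recessive, additive and
    dominant codings; and summarizes outlier-performance rates per mouse and
    per homozygous mutation, genome saturation, mutation-load effects and
    spontaneous-mutation-rate arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
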