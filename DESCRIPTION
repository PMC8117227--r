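Package: gwasim
Title: Simulation-Based Evaluation of Mixed-Model Association Methods in
    Structured Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of structured fish, beef-cattle and
    dairy-cattle breeding populations (historical linkage-disequilibrium
    generation followed by species-specific selection and mating designs),
    and four genome-wide association methods run on the simulated data:
    single-SNP least squares without relatedness correction, EMMAX-style
    generalized least squares with a genomic kinship, GBLUP back-solved SNP
    effects, and single-step GWAS using the combined pedigree-genomic
    relationship matrix H.  Includes pedigree and genomic relationship
    machinery (tabular A, VanRaden and marker-mean-centered G, blending,
    base tuning, H inverse), mixed-model equations with REML variance
    components, deregressed proofs for sex-limited traits, genotype quality
    control, and an evaluation layer (Bonferroni thresholds, true/false
    positive windows around simulated QTN, ROC curves, LD decay, PCA of G,
    effective population size from inbreeding trends).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
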