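Package: paleocomm
Title: Community Reconstruction from Low-Coverage Ancient Genomes and
    Isotope Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the biological and social structure
    of past communities from low-coverage ancient DNA and bioarchaeological
    isotope measurements.  Implements supervised admixture estimation from
    genotype likelihoods by maximum likelihood with multiple restarts and
    10 Mb block-bootstrap confidence intervals, pairwise relatedness
    estimation over identity-by-descent coefficients (k0, k1, k2) with
    overlap filtering, degree classification, multi-estimator
    reconciliation and pedigree assembly, identity-by-descent sharing
    networks with an adjusted kinship-proportion edge statistic, strontium
    isotope locality baselines and classification, collagen quality
    control and dietary group comparisons, permutation tests and Cramer's
    V for mortuary associations, and a synthetic-cohort simulator with
    known admixture, pedigree, IBD and isotope truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
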