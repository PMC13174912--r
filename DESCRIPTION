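Package: calixtopo
Title: Topological Descriptors and Kernel-Ridge Screening of Calix[4]arene CO2 Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Featurizes macrocyclic host geometries as electronegativity-weighted
    persistence images built from Vietoris-Rips persistent homology of the atomic
    point cloud, trains a Laplacian-kernel ridge regression surrogate for CO2
    adsorption enthalpy with three-fold cross-validation, grid search and the
    one-standard-error rule, and drives a screen-validate-augment discovery loop
    over symmetrically functionalized calix[4]arene, azacalix[4]arene,
    oxacalix[4]arene and thiacalix[4]arene libraries. Includes a synthetic
    structure generator so the full pipeline is testable without quantum
    chemistry data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
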