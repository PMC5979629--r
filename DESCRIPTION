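Package: seadrift
Title: Seascape Genetics and Biophysical Connectivity Modelling
Version: 1.0.0
Authors@R: person("Seadrift", "Developers", email = "seadrift@example.org",
    role = c("aut", "cre"))
Description: Dual assessment of marine population connectivity for partially
    clonal, passively rafting species such as eelgrass. Combines a
    population-genetic toolchain for microsatellite data (clone discrimination
    via the probability of independent sexual origin, genotypic and allelic
    richness, heterozygosity and inbreeding statistics, shared-allele
    distances, probability of identity, drift-based power simulation,
    directional relative migration from G_ST) with a biophysical one
    (synthetic seascapes and surface currents, Lagrangian particle tracking,
    single- and multigeneration stepping-stone dispersal matrices, barrier
    clustering, least-cost sea distances) and cross-validates the two through
    Mantel and asymmetric-Mantel isolation-by-distance/oceanography tests and
    intermediate-threshold connectivity networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
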