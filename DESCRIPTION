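Package: courtpop
Title: Courtship Display Structure and Population-Genetic Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking the structure of courtship displays to
    population-genetic divergence in wild insect populations. Parses
    time-stamped behavior event logs into composite behavioral states,
    computes proportional courtship metrics, builds Markov transition-count
    matrices with permutation-filtered significant transitions, and measures
    divergence between individual courtship chains with Dirichlet-smoothed
    Kullback-Leibler divergences. On the genetic side it filters biallelic
    SNP panels by reproducibility, call rate and minor-allele frequency, and
    computes observed and expected heterozygosity, F_IS, Weir-Cockerham
    pairwise F_ST, Weir-Goudet population-specific F_ST, distance-based
    AMOVA with permutation inference, Nei (1972) distances, Kosman
    inter-individual distances, private-allele counts, genotype PCA and a
    Mantel test of isolation by distance. Semi-Markov behavior and
    Balding-Nichols SNP simulators generate data with the statistical
    structure the analysis assumes, and a pipeline driver reproduces the
    full analysis at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR,
    igraph
Config/testthat/edition: 3
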