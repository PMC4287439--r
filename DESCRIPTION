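Package: meiomut
Title: Mutation Rate and Recombination Analysis for Meiotic Mutagenesis
    Experiments in Yeast
Version: 1.0.0
Authors@R: person("Meiomut", "Developers", role = c("aut", "cre"),
    email = "meiomut@example.org")
Description: Tools for quantifying the elevation of mutation rate during
    meiosis ("the meiotic effect") from forward-mutation reporter assays in
    Saccharomyces cerevisiae.  Implements Luria-Delbruck fluctuation-test
    analysis with the Ma-Sandri-Sarkar maximum-likelihood estimator and
    Foster-style confidence intervals, a single-division meiotic mutation
    rate estimator based on per-culture frequency subtraction, tetrad
    analysis (parental ditype / non-parental ditype / tetratype
    classification, Perkins map distances, standard errors and per-kilobase
    recombination densities), random-spore crossover-interval classification
    with crossover-interference statistics, and mutation-spectrum
    classification (frameshift, base substitution, complex).  A synthetic
    data generator produces fluctuation cultures, tetrads, random spores and
    mutation lists with the statistical structure the estimators assume, so
    every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
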