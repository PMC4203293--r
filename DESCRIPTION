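Package: refugia
Type: Package
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Postglacial Recolonization Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests competing postglacial recolonization histories with
    combined mitochondrial-sequence and microsatellite data. Provides a
    structured-coalescent simulator for three-lineage isolation scenarios
    (Holocene, Last Glacial Maximum and Eemian divergence times), finite-site
    sequence and generalized stepwise microsatellite mutation models, a
    DIYABC-style summary-statistic registry, approximate Bayesian computation
    with logistic-regression scenario choice and local-linear parameter
    posteriors, confidence evaluation via pseudo-observed datasets, and the
    supporting empirical statistics: nucleotide and haplotype diversity,
    Tajima's D, Fu and Li's F, Hudson and Weir-Cockerham FST, three-level
    AMOVA with permutation tests, haplotype rarefaction, fragment trimming
    and isolation-with-migration unit conversion.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
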