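Package: antmine
Title: Text-Mined Binary Traits and State-Dependent Diversification on Ant Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to mine binary species traits (ant-plant mutualism
    categories: domatia nesting, extrafloral nectar visitation, food-body
    consumption, seed dispersal) from literature abstracts with an n-gram
    dictionary approach, validate the mined data (species accumulation
    curves, false-positive audits by co-occurrence count, comparison with
    hand-compiled lists), and relate the resulting traits to lineage
    diversification with a state-dependent speciation-extinction engine:
    BiSSE and the HiSSE model family (CID-2/CID-4 character-independent
    nulls, one- and two-hidden-class models) with maximum-likelihood fitting
    and AIC comparison, slice-sampling MCMC with exponential priors,
    marginal ancestral state reconstruction, and tip-averaged rates.
    Includes a synthetic-corpus generator with known ground truth and a
    state-dependent birth-death tree simulator for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
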