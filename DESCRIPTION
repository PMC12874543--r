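Package: binreps
Title: Reconciling Binary Technical Replicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scoring, classification, and prevalence estimation from
    repeated binary measurements (technical replicates) of a latent
    binary state, without a gold standard. Implements four per-individual
    scores -- the replicate average, the replicate median, a penalized
    maximum-likelihood (MAP) score fitted by expectation-maximization,
    and a fully Bayesian score computed by Gibbs sampling with data
    augmentation -- together with risk-optimal three-way classification
    (negative / indecisive / positive), estimators of prevalence and of
    the false-positivity and false-negativity rates, predictive scoring
    of new individuals, and simulation drivers for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
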