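Package: gpdrc
Title: Uncertainty-Aware Dose-Response Modelling and Biomarker Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits dose-response curves from high-throughput drug screens with a
    Gaussian process under a two-component Beta-mixture likelihood, estimated by
    variational inference. Posterior curve samples yield IC50 and AUC summary
    statistics together with their estimation uncertainty, which is propagated
    into a hierarchical Bayesian test for genetic biomarkers of drug response
    (sampled by Hamiltonian Monte Carlo). Includes the classical two-parameter
    sigmoid fit with bootstrap uncertainty and an ANOVA biomarker test for
    comparison, concordance statistics between fitting methods, raw-plate
    normalisation and QC, and a synthetic screen generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
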