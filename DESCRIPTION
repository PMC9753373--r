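Package: penfam
Title: Penetrance of Autosomal Dominant Variants from Family Disease States
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates lifetime penetrance of autosomal dominant variants
    from the distribution of a variant among familial cases, sporadic cases
    and unaffected individuals, together with the average sibship size of the
    sampled population and the residual disease risk of non-carriers.
    Provides closed-form nuclear-family disease-state probabilities, weighted
    observed state rates with delta-method confidence intervals, lookup-table
    inversion of the state-rate curve, and simulation-based bias correction
    calibrated by polynomial regression. Bundles the published case-study
    inputs for LRRK2 (Parkinson's disease), BMPR2 (pulmonary arterial
    hypertension), and SOD1 and C9orf72 (amyotrophic lateral sclerosis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
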