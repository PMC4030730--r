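Package: clrdmc
Title: Compositional Differential Abundance via Dirichlet Monte Carlo
    Sampling and Centered Log-Ratios
Version: 0.1.0
Authors@R:
    person("clrdmc", "maintainers", email = "clrdmc@example.org",
           role = c("aut", "cre"))
Description: Differential relative-abundance analysis for feature-by-sample
    sequencing count tables (16S rRNA gene OTU tables, RNA-seq gene counts,
    selective-growth variant libraries) treated as compositions.  Per-sample
    technical variation is modelled by Monte Carlo sampling of proportions
    from the Dirichlet posterior with a uniform 1/2 prior; each instance is
    centered log-ratio transformed (base 2), tested between two conditions
    with Welch's t and Wilcoxon rank-sum tests, Benjamini-Hochberg corrected
    within each instance, and summarised as expected values across instances
    together with median between/within-condition differences and a
    standardised effect size.  Includes MW and MA diagnostic plots, a
    synthetic-data generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
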