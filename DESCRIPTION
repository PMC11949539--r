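Package: prevstab
Title: Sampling-Effort Sufficiency for Species Occurrence and Prevalence
    Rates
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Decides whether a presence/absence sampling effort suffices
    to estimate species occurrence or prevalence rates.  Mean prevalence
    accumulation curves are built by repeated subsampling without
    replacement from the observed units, and the minimum sufficient
    sample size (the stability point) is detected with a windowed
    flatness criterion on successive curve means.  Includes a simulation
    harness that validates the estimator on synthetic populations of
    known size and prevalence, closed-form finite-population sampling
    errors, panel figures of the curves with stability annotations, and a
    command-line interface for running analyses in the field.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
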