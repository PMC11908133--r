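Package: clonedyn
Title: Clonal Hematopoiesis Dynamics from Longitudinal VAF Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the clonal structure and per-clone fitness of somatic
    mutations in clonal hematopoiesis from longitudinal variant allele
    frequency (VAF) trajectories. Candidate clonal structures (set
    partitions of a participant's variants) are scored by grid-based
    marginal likelihood under a binomial read-count emission model with
    deterministic exponential clone growth; the selected structure yields
    maximum a posteriori fitness per clone, the age at the time of
    mutation acquisition (ATMA) per variant, and the predicted maximum
    clone size at age 120 (MACS120). Includes competition-aware VAF
    forecasting, a synthetic-cohort generator emulating three longitudinal
    aging-cohort designs with known ground truth, mutation co-occurrence
    network summaries with Brunner-Munzel tests, and downstream blood
    marker (linear mixed model) and survival (Cox proportional hazards)
    association stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    survival,
    lme4,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
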