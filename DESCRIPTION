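Package: slfmature
Title: Virtual Dissection and Maturation Analysis of the Superior
    Longitudinal Fasciculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to virtually dissect the three branches of the superior
    longitudinal fasciculus (SLF I, II, III) from whole-brain tractograms
    using boolean include/exclude region-of-interest rules, to fit DTI and
    a simplified NODDI microstructure model to multi-shell diffusion MRI
    signals, to sample metric volumes along streamlines into per-subject
    tract means, and to quantify per-branch neonatal maturation with a
    multivariate Mahalanobis distance against an adult reference cohort.
    Includes readers and writers for TCK tractograms, NIfTI-1 volumes and
    FSL/MRtrix gradient tables, and a synthetic phantom generator so the
    full pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
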