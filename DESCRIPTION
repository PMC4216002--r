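Package: lungtrack
Title: Stochastic Tracking of Mucus Obstruction in Branching Airway Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating and forecasting mucus obstruction in the
    bronchial tree of cystic-fibrosis and COPD patients from spirometry
    (FEV1/FVC) and coarse imaging summaries. Models the lung as a fractal
    binary (Weibel-type) airway tree, computes Poiseuille airflow resistance
    and the fraction of accessible alveoli for any mucus configuration, and
    uses constant-temperature Metropolis-Hastings sampling to (i) tabulate
    offline two-dimensional probability densities of (airflow resistance
    ratio, percent accessible alveoli) per voxel mucus fraction, (ii) solve
    the inverse problem of sampling per-voxel and per-generation mucus
    distributions consistent with a patient's spirometry and optional
    imaging voxels, and (iii) forecast future FEV1/FVC distributions under
    linear mucus growth. Includes a synthetic-patient generator so the full
    pipeline is testable without clinical data.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
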