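Package: valuedyn
Title: Stable and Dynamic Value Codes in Prefrontal Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how a remembered value is represented across a
    delay in neural population activity. Provides an inhomogeneous-Poisson
    spike-train simulator with planted coding regimes (stable, sequential,
    reversing, non-monotonic, type- and time-coding units), Gaussian-kernel
    rate estimation and pseudo-population assembly, per-unit encoding
    statistics (per-bin ANOVA with run-length significance, encoding strength,
    stability measure, d-prime), cross-temporal population decoding with a
    one-versus-one ridge classifier, permutation-based significance with
    p-value aggregation across datasets, value-subspace projection with
    leakage-free nested cross-validation, greedy backward ensemble selection
    under stability or temporal-locality objectives, and population-dynamics
    summaries (trajectory speed, time regression, encoding-decoding
    correlation battery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
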