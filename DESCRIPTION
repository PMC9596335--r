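Package: habiq
Title: Land-Use Change and Habitat-Quality Assessment on Categorical Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how land-use change affects wildlife habitat
    on regular categorical rasters. Implements land-use transfer (transition)
    matrices with inflow/outflow accounting, a threat-based habitat
    degradation and quality model with linear and exponential distance-decay
    kernels and a half-saturation transform, Fisher-Jenks natural-breaks and
    fixed-threshold classification of quality surfaces, and zonal summary
    statistics. Ships a seedable synthetic-landscape generator (spatially
    autocorrelated categorical fields evolved under a Markov transition
    model) so the whole pipeline can be exercised without proprietary
    land-cover products, plus a declarative pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
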