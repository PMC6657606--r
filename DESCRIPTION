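Package: chemoauth
Title: Geographical Origin Authentication from Elemental Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric pipeline for authenticating the geographical origin
    of agricultural and herbal products from mineral-element concentration
    fingerprints (e.g. ICP-MS panels). Provides robust Stahel-Donoho
    outlier screening by random projections, per-class Kennard-Stone
    maximin splitting into learning and prediction sets, autoscaling and
    principal component exploration, a NIPALS partial least squares core,
    binary PLS discriminant analysis with Monte Carlo cross-validated
    latent-variable selection, and multiclass assembly under both
    one-versus-rest and one-versus-one strategies with accuracy and
    loading-importance reporting. Includes a synthetic panel generator
    emulating seven-origin element panels for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
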