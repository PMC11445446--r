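Package: crevo
Title: First Steps of Evolution in Randomly Assembled Consumer-Resource Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and theory for the early evolution of large, randomly
    assembled microbial communities competing for substitutable resources.
    Provides random species pools with binary resource-usage sampling,
    uninvadable ecological equilibria of the coarse-grained relative-abundance
    dynamics (computed by concave maximization and cross-validated against
    numerical integration), knock-out/knock-in/multi-resource mutant
    construction, exact and approximate invasion fitness, distributions of
    fitness effects, mutant-parent coexistence and extinction statistics after
    mutant invasion, mutation-limited multi-step evolution with lineage
    tracking, and closed-form mean-field predictions for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
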