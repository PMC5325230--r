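Package: threeway
Title: Three-Way Decisions with Probabilistic Rough Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accept/reject/defer classification of objects in an information
    table using probabilistic rough sets.  Computes Pawlak and
    (alpha, beta)-probabilistic positive, negative and boundary regions,
    learns decision thresholds either by minimizing Shannon- or Gini-based
    region uncertainty (information-theoretic rough sets, ITRS) or by
    repeated two-player threshold-perturbation games solved at pure-strategy
    Nash equilibria (game-theoretic rough sets, GTRS), and iteratively
    refines the deferred boundary region as new features become available,
    as in protein function annotation with evolving biological evidence.
    Includes accuracy/generality evaluation with stratified cross-validation,
    a synthetic generator for evolving-feature benchmarks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
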