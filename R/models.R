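# Closed set of three-way decision models exposed across the package.
# pawlak   : classical regions at the qualitative (1, 0) point
# itrs_e/g : thresholds minimizing Shannon / Gini region uncertainty
# gtrs_e/g : repeated uncertainty games (Shannon / Gini payoffs)
# gtrs_ag  : repeated accuracy-vs-generality games

#' Model names understood by the package
#' @return Character vector of valid model identifiers.
#' @export
twd_models <- function() {
  c("pawlak", "itrs_e", "itrs_g", "gtrs_e", "gtrs_g", "gtrs_ag")
}

.check_model <- function(model) {
  if (!is.character(model) || length(model) != 1L ||
      !model %in% twd_models())
    stop("unknown model '", model, "'; valid models: ",
         paste(twd_models(), collapse = ", "), call. = FALSE)
  model
}

.concept_of <- function(members, label, universe) {
  structure(list(members = members, label = label, universe = universe),
            class = "concept")
}

#' Learn decision thresholds under a named model
#'
#' Unified entry point over the threshold learners: the Pawlak model uses
#' the fixed pair (1, 0); `itrs_*` call [itrs_learn_thresholds()];
#' `gtrs_*` call [gtrs_learn_thresholds()].
#'
#' @param partition a [compute_partition()] result.
#' @param concept a [concept_from_decision()] result.
#' @param model one of [twd_models()].
#' @param ... passed on to the underlying learner (e.g. `steps`,
#'   `max_iterations` for GTRS; `search` for ITRS).
#' @return A [threshold_pair()].
#' @export
learn_thresholds <- function(partition, concept, model, ...) {
  .check_model(model)
  switch(model,
    pawlak = threshold_pair(1, 0),
    itrs_e = itrs_learn_thresholds(partition, concept, "shannon",
                                   ...)$thresholds,
    itrs_g = itrs_learn_thresholds(partition, concept, "gini",
                                   ...)$thresholds,
    gtrs_e = ,
    gtrs_g = ,
    gtrs_ag = gtrs_learn_thresholds(partition, concept, model,
                                    ...)$thresholds)
}

# fit regions under a named model; pawlak keeps its qualitative semantics
# (block subset / disjointness) rather than going through thresholds
.fit_regions <- function(partition, concept, model, ...) {
  .check_model(model)
  if (model == "pawlak") return(pawlak_regions(partition, concept))
  thr <- learn_thresholds(partition, concept, model, ...)
  probabilistic_regions(partition, concept, thr)
}
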