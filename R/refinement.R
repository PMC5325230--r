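# Iterative boundary refinement under evolving features.
#
# When a new feature arrives, either (i) the current positive and negative
# regions are already good enough (region precisions above the floors c1,
# c2), in which case only the deferred objects are re-trisected on the
# enlarged attribute set, with the old boundary treated as the whole
# universe for threshold learning; or (ii) quality is insufficient and the
# regions are recomputed from scratch on the full table.

#' Quality floors for the positive and negative regions
#'
#' @param c1 quality floor for the positive region.
#' @param c2 quality floor for the negative region.
#' @param quality_measure currently `"precision"`: Q_P = P(C|POS),
#'   Q_N = P(C^c|NEG).
#' @return Object of class `quality_config`.
#' @export
quality_config <- function(c1 = 0.9, c2 = 0.9,
                           quality_measure = "precision") {
  if (!is.numeric(c1) || !is.numeric(c2) ||
      c1 < 0 || c1 > 1 || c2 < 0 || c2 > 1)
    stop("c1 and c2 must lie in [0, 1]", call. = FALSE)
  quality_measure <- match.arg(quality_measure)
  structure(list(c1 = c1, c2 = c2, quality_measure = quality_measure),
            class = "quality_config")
}

#' Precision of the positive and negative regions
#'
#' Q_P = |POS n C| / |POS| and Q_N = |NEG n C^c| / |NEG|.  An empty region
#' has undefined quality, returned as `NA`; an undefined quality fails any
#' positive floor (an empty positive region carries no evidence of
#' adequacy), forcing full recomputation in [refine_with_new_feature()].
#'
#' @param tri a `tripartition`.
#' @param concept a [concept_from_decision()] result.
#' @return Named numeric `c(Q_P = ..., Q_N = ...)`, `NA` where undefined.
#' @export
region_quality <- function(tri, concept) {
  stopifnot(inherits(tri, "tripartition"), inherits(concept, "concept"))
  q_p <- if (length(tri$pos))
    sum(tri$pos %in% concept$members) / length(tri$pos) else NA_real_
  q_n <- if (length(tri$neg))
    sum(!tri$neg %in% concept$members) / length(tri$neg) else NA_real_
  c(Q_P = q_p, Q_N = q_n)
}

#' Refine a trisection when a new feature arrives
#'
#' Implements one step of the iterative three-way decision algorithm.  If
#' the prior regions pass the quality floors, thresholds are re-learned on
#' the reduced table whose universe is the prior boundary, the boundary is
#' re-trisected on the enlarged attribute set, and the new positive/negative
#' sub-regions are merged into the prior ones (the new boundary is the
#' sub-boundary).  Otherwise thresholds and regions are recomputed on the
#' full table.
#'
#' @param table an [information_table()] carrying the previous attributes
#'   plus the newly arrived one(s), over the same universe as `prior`.
#' @param prior the `tripartition` computed before the new feature arrived.
#' @param model one of [twd_models()].
#' @param quality a [quality_config()].
#' @param force_full when `TRUE`, always take the full-recompute branch.
#' @param ... passed to the threshold learner.
#' @return A `tripartition` with attributes `branch` (`"boundary-only"` or
#'   `"full-recompute"`) and, on the boundary branch, `prior_quality`.
#' @export
refine_with_new_feature <- function(table, prior, model,
                                    quality = quality_config(),
                                    force_full = FALSE, ...) {
  stopifnot(inherits(table, "information_table"),
            inherits(prior, "tripartition"),
            inherits(quality, "quality_config"))
  .check_model(model)
  if (!setequal(table$ids, prior$universe))
    stop("table and prior tri-partition are over different universes",
         call. = FALSE)
  concept <- concept_from_decision(table, prior$concept_label)
  q <- region_quality(prior, concept)
  take_boundary <- !force_full &&
    !is.na(q[["Q_P"]]) && !is.na(q[["Q_N"]]) &&
    q[["Q_P"]] >= quality$c1 && q[["Q_N"]] >= quality$c2
  if (take_boundary) {
    if (!length(prior$bnd)) {
      out <- prior
      attr(out, "branch") <- "boundary-only"
      attr(out, "prior_quality") <- q
      return(out)
    }
    sub_table <- subset_objects(table, prior$bnd)
    sub_concept <- .concept_of(intersect(concept$members, prior$bnd),
                               concept$label, prior$bnd)
    sub_part <- compute_partition(sub_table)
    sub_tri <- .fit_regions(sub_part, sub_concept, model, ...)
    out <- .new_tripartition(
      pos = union(prior$pos, sub_tri$pos),
      neg = union(prior$neg, sub_tri$neg),
      bnd = sub_tri$bnd,
      thresholds = sub_tri$thresholds,
      concept_label = concept$label,
      universe = table$ids)
    attr(out, "branch") <- "boundary-only"
    attr(out, "prior_quality") <- q
    return(out)
  }
  part <- compute_partition(table)
  out <- .fit_regions(part, concept, model, ...)
  attr(out, "branch") <- "full-recompute"
  attr(out, "prior_quality") <- q
  out
}

#' Trace three-way decisions across an evolving feature schedule
#'
#' Stage 1 computes regions from scratch on the first feature group; each
#' later stage adds the next group to the cumulative attribute set and
#' applies [refine_with_new_feature()].
#'
#' @param table an [information_table()].
#' @param schedule list of disjoint attribute groups (character vectors) in
#'   order of arrival; their union must be a subset of the table's
#'   attributes.
#' @param model one of [twd_models()].
#' @param concept_label decision value defining the concept.
#' @param quality a [quality_config()].
#' @param force_full when `TRUE`, every stage recomputes from scratch.
#' @param ... passed to the threshold learner.
#' @return Object of class `evolution_trace`: list `stages`, each with
#'   `attrs` (cumulative attribute set), `tri`, `thresholds` and `branch`.
#' @examples
#' tab <- table1_fixture()
#' tr <- evolve(tab,
#'              list("Localization", "Interacting proteins", "No. of Domains"),
#'              model = "pawlak", concept_label = "Yes")
#' as.data.frame(tr)
#' @export
evolve <- function(table, schedule, model, concept_label,
                   quality = quality_config(), force_full = FALSE, ...) {
  stopifnot(inherits(table, "information_table"))
  .check_model(model)
  if (!length(schedule)) stop("empty schedule", call. = FALSE)
  schedule <- lapply(schedule, as.character)
  all_attrs <- unlist(schedule)
  if (anyDuplicated(all_attrs))
    stop("schedule groups must be disjoint", call. = FALSE)
  unknown <- setdiff(all_attrs, attributes_of(table))
  if (length(unknown))
    stop("unknown attribute(s) in schedule: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  concept <- concept_from_decision(table, concept_label)
  stages <- vector("list", length(schedule))
  cum <- character(0)
  for (s in seq_along(schedule)) {
    cum <- c(cum, schedule[[s]])
    stage_tab <- restrict_attributes(table, cum)
    if (s == 1L) {
      part <- compute_partition(stage_tab)
      tri <- .fit_regions(part, concept, model, ...)
      branch <- "full-recompute"
    } else {
      tri <- refine_with_new_feature(stage_tab, stages[[s - 1L]]$tri,
                                     model, quality,
                                     force_full = force_full, ...)
      branch <- attr(tri, "branch")
    }
    stages[[s]] <- list(attrs = cum, tri = tri,
                        thresholds = tri$thresholds, branch = branch)
  }
  structure(list(stages = stages, model = model,
                 concept_label = concept_label),
            class = "evolution_trace")
}

#' @export
as.data.frame.evolution_trace <- function(x, ...) {
  rows <- lapply(seq_along(x$stages), function(s) {
    st <- x$stages[[s]]
    tri <- st$tri
    data.frame(stage = s,
               n_attrs = length(st$attrs),
               branch = st$branch,
               pos = length(tri$pos), neg = length(tri$neg),
               bnd = length(tri$bnd),
               generality = generality(tri),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-stage summary of an evolution trace
#'
#' @param object an `evolution_trace`.
#' @param concept optional [concept_from_decision()] result; when supplied,
#'   per-stage accuracy is included.
#' @param ... ignored.
#' @return data.frame with one row per stage: region sizes, branch taken,
#'   generality and (optionally) accuracy.
#' @export
summary.evolution_trace <- function(object, concept = NULL, ...) {
  df <- as.data.frame(object)
  if (!is.null(concept))
    df$accuracy <- vapply(object$stages,
                          function(st) as.numeric(accuracy(st$tri, concept)),
                          1)
  df
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat("Evolution trace (model ", x$model, ", concept '",
      x$concept_label, "')\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}
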