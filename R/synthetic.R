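# Synthetic information tables with a latent binary concept, evolving
# feature groups of controllable informativeness, and label noise.
#
# Each categorical feature has three disjoint sets of levels: one or more
# concept-positive levels, as many concept-negative levels, and shared
# background levels.  With probability equal to its informativeness a
# feature value is drawn from the concept-conditional support (positive
# levels for concept members, negative levels otherwise); with the
# complementary probability it is drawn uniformly from the background.  The
# two concept-conditional distributions are therefore overlapping
# multinomials whose overlap is 1 - informativeness: at informativeness 1
# the supports are disjoint and every equivalence class on that feature is
# pure in the latent concept, while at informativeness 0 the feature is
# pure noise.

#' Describe one group of synthetic features
#'
#' @param informativeness probability, per feature, that a value is drawn
#'   from the concept-dependent distribution rather than the shared
#'   background (one value per feature in the group).
#' @param cardinality number of categorical levels per feature (>= 2; with
#'   2 levels there is no background and the overlap is realized by mixing
#'   the two supports).
#' @param names optional feature names.
#' @param numeric when `TRUE` the feature is emitted as a jittered numeric
#'   value (level index plus uniform jitter) so it exercises the
#'   discretization path.
#' @return data.frame describing the group, one row per feature.
#' @export
feature_group <- function(informativeness, cardinality = 4, names = NULL,
                          numeric = FALSE) {
  k <- length(informativeness)
  if (!k) stop("a feature group must contain at least one feature",
               call. = FALSE)
  if (any(informativeness < 0 | informativeness > 1))
    stop("informativeness must lie in [0, 1]", call. = FALSE)
  cardinality <- rep_len(cardinality, k)
  if (any(cardinality < 2))
    stop("cardinality must be >= 2", call. = FALSE)
  if (is.null(names)) names <- rep(NA_character_, k)
  data.frame(name = names, informativeness = informativeness,
             cardinality = as.integer(cardinality),
             numeric = rep_len(numeric, k), stringsAsFactors = FALSE)
}

#' Specify a synthetic evolving-feature table
#'
#' @param n_objects number of objects.
#' @param concept_prevalence fraction of objects in the latent concept,
#'   in (0, 1).
#' @param feature_groups ordered list of [feature_group()] data.frames,
#'   released cumulatively.
#' @param label_noise probability that a decision label is flipped after
#'   the latent concept is drawn.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_objects = 1000, concept_prevalence = 0.4,
                           feature_groups = default_feature_groups(),
                           label_noise = 0.05, seed = 1) {
  if (n_objects < 1) stop("n_objects must be positive", call. = FALSE)
  if (concept_prevalence <= 0 || concept_prevalence >= 1)
    stop("concept_prevalence must lie strictly in (0, 1)", call. = FALSE)
  if (label_noise < 0 || label_noise > 1)
    stop("label_noise must lie in [0, 1]", call. = FALSE)
  if (!length(feature_groups))
    stop("feature_groups must be nonempty", call. = FALSE)
  feature_groups <- lapply(feature_groups, function(g) {
    if (!is.data.frame(g)) stop("each group must come from feature_group()",
                                call. = FALSE)
    g
  })
  # assign default feature names F1.. in release order
  idx <- 0L
  for (gi in seq_along(feature_groups)) {
    g <- feature_groups[[gi]]
    for (fi in seq_len(nrow(g))) {
      idx <- idx + 1L
      if (is.na(g$name[fi])) g$name[fi] <- paste0("F", idx)
    }
    feature_groups[[gi]] <- g
  }
  structure(list(n_objects = as.integer(n_objects),
                 concept_prevalence = concept_prevalence,
                 feature_groups = feature_groups,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default feature groups of the evolving benchmark
#'
#' Four cumulative releases of one categorical feature each, with
#' informativeness rising 0.2, 0.4, 0.6, 0.8 — emulating feature evidence
#' that matures over time.  One feature per release with four levels keeps
#' the signature space (4^4 = 256) well populated at the default universe
#' size, so held-out signatures are usually seen in training.
#'
#' @param informativeness informativeness of the successive releases.
#' @param cardinality levels per feature.
#' @return List of [feature_group()] data.frames.
#' @export
default_feature_groups <- function(informativeness = c(0.2, 0.4, 0.6, 0.8),
                                   cardinality = 4) {
  lapply(informativeness, feature_group, cardinality = cardinality)
}

#' Generate a synthetic information table
#'
#' @param spec a [synthetic_spec()].
#' @return List with `table` (an [information_table()]) and `truth`
#'   (ground-truth record: latent concept indicator `z`, pre-noise labels,
#'   and per-feature level roles), suitable for parameter-recovery tests.
#'   Ground truth is never embedded in the table itself.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_objects
  z <- stats::rbinom(n, 1L, spec$concept_prevalence)
  flip <- stats::rbinom(n, 1L, spec$label_noise) == 1L
  label_bit <- ifelse(flip, 1L - z, z)
  decision <- ifelse(label_bit == 1L, "Yes", "No")
  cols <- list()
  roles <- list()
  for (g in spec$feature_groups) {
    for (fi in seq_len(nrow(g))) {
      L <- g$cardinality[fi]
      w <- g$informativeness[fi]
      n_sig <- 1L                              # one pos + one neg level
      n_bg <- L - 2L * n_sig                   # may be 0 when L == 2
      lev_pos <- seq_len(n_sig)
      lev_neg <- n_sig + seq_len(n_sig)
      lev_bg <- if (n_bg > 0) 2L * n_sig + seq_len(n_bg) else
        c(lev_pos, lev_neg)                    # no reserved background
      informative <- stats::rbinom(n, 1L, w) == 1L
      lev <- integer(n)
      # draw from a level set by index (guards the scalar-x sample() rule)
      draw <- function(levels, k) levels[sample.int(length(levels), k,
                                                    replace = TRUE)]
      lev[informative & z == 1L] <- draw(lev_pos, sum(informative & z == 1L))
      lev[informative & z == 0L] <- draw(lev_neg, sum(informative & z == 0L))
      lev[!informative] <- draw(lev_bg, sum(!informative))
      cols[[g$name[fi]]] <- if (g$numeric[fi])
        lev + stats::runif(n, -0.3, 0.3)
      else
        paste0("v", lev)
      roles[[g$name[fi]]] <- list(positive = lev_pos, negative = lev_neg,
                                  background = if (n_bg > 0) lev_bg
                                               else integer(0),
                                  informativeness = w)
    }
  }
  tab <- information_table(as.data.frame(cols, check.names = FALSE,
                                         optional = TRUE),
                           decision = decision,
                           decision_name = "Function")
  list(table = tab,
       truth = list(z = z, pre_noise_labels = ifelse(z == 1L, "Yes", "No"),
                    flipped = flip, level_roles = roles, spec = spec))
}

#' The 8-protein demonstration table
#'
#' A small worked example: eight proteins described by their localization,
#' number of interacting proteins and number of domains, with a binary
#' "Function" decision.  The three attributes become available at
#' successive times, which makes the table the canonical input for
#' [evolve()].
#'
#' @return An [information_table()] with objects `O1..O8` and attributes
#'   `Localization`, `Interacting proteins`, `No. of Domains`.
#' @export
table1_fixture <- function() {
  data <- data.frame(
    Localization = c("Mitochondria", "Mitochondria", "CytoPlasm",
                     "CytoPlasm", "CytoPlasm", "CytoPlasm", "CytoPlasm",
                     "Mitochondria"),
    `Interacting proteins` = c(0, 0, 1, 2, 2, 0, 2, 0),
    `No. of Domains` = c(0, 1, 0, 0, 0, 0, 1, 1),
    check.names = FALSE)
  information_table(data,
                    decision = c("Yes", "No", "Yes", "No", "No", "Yes",
                                 "No", "No"),
                    ids = paste0("O", 1:8),
                    decision_name = "Function")
}

#' Evolving-feature benchmark table and schedule
#'
#' Generates the default synthetic benchmark — a table whose feature groups
#' have non-decreasing informativeness — together with the cumulative
#' schedule that [evolve()] and the cross-validation harness consume.
#'
#' @param spec a [synthetic_spec()]; the default has n = 1000 objects, four
#'   single-feature groups of informativeness 0.2/0.4/0.6/0.8, prevalence
#'   0.4, label noise 0.05.
#' @param seed convenience override of `spec$seed`.
#' @return List with `table`, `schedule` (list of attribute-name groups),
#'   and `truth`.
#' @export
evolving_benchmark <- function(spec = NULL, seed = NULL) {
  if (is.null(spec)) spec <- synthetic_spec(seed = 7)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  if (length(spec$feature_groups) < 2)
    stop("an evolving benchmark needs at least 2 feature groups",
         call. = FALSE)
  inf <- vapply(spec$feature_groups,
                function(g) mean(g$informativeness), 1)
  if (is.unsorted(inf))
    warning("feature-group informativeness is not non-decreasing",
            call. = FALSE)
  gen <- generate_table(spec)
  schedule <- lapply(spec$feature_groups, function(g) g$name)
  list(table = gen$table, schedule = schedule, truth = gen$truth)
}
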