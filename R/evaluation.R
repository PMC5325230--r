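# Accuracy / generality of a trisection and seeded cross-validation.

#' Accuracy of a three-way decision
#'
#' Fraction of correct decisions among the objects given a definite
#' (accept or reject) decision:
#' |(POS n C) u (NEG n C^c)| / |POS u NEG|.  Undefined (returned as `NA`
#' with attribute `undefined = TRUE`) when both immediate regions are
#' empty — never silently 0.
#'
#' @param tri a `tripartition`.
#' @param concept a [concept_from_decision()] result over the same universe.
#' @return Fraction in \[0, 1\], or `NA` when undefined.
#' @export
accuracy <- function(tri, concept) {
  stopifnot(inherits(tri, "tripartition"), inherits(concept, "concept"))
  denom <- length(tri$pos) + length(tri$neg)
  if (denom == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  correct <- sum(tri$pos %in% concept$members) +
    sum(!tri$neg %in% concept$members)
  correct / denom
}

#' Generality of a three-way decision
#'
#' Fraction of the universe given a definite decision:
#' |POS u NEG| / |U| = 1 - |BND| / |U|.
#'
#' @inheritParams accuracy
#' @return Fraction in \[0, 1\].
#' @export
generality <- function(tri, concept = NULL) {
  stopifnot(inherits(tri, "tripartition"))
  if (!length(tri$universe)) stop("empty universe", call. = FALSE)
  (length(tri$pos) + length(tri$neg)) / length(tri$universe)
}

# internal: fit a model on a training table and return a lookup from block
# signature to region, plus the thresholds used
.fit_twd <- function(train_table, concept_label, model,
                     attrs = attributes_of(train_table), ...) {
  concept <- concept_from_decision(train_table, concept_label)
  stats <- .block_stats(train_table, attrs, concept)
  if (model == "pawlak") {
    thr <- threshold_pair(1, 0)
    region <- ifelse(stats$n_concept == stats$size, "POS",
              ifelse(stats$n_concept == 0L, "NEG", "BND"))
  } else {
    part <- compute_partition(train_table, attrs)
    thr <- learn_thresholds(part, concept, model, ...)
    region <- ifelse(stats$prob >= thr$alpha - .TOL, "POS",
              ifelse(stats$prob <= thr$beta + .TOL, "NEG", "BND"))
  }
  list(signature = stats$signature, region = region, thresholds = thr,
       attrs = attrs, model = model)
}

#' Classify held-out objects against a fitted training table
#'
#' Each test object is matched to the training equivalence class with an
#' identical value signature and inherits that block's region decision.
#' Objects whose signature never occurred in training are deferred: an
#' unseen combination of feature values is exactly the "insufficient
#' evidence" situation the defer option exists for.
#'
#' @param train_table training [information_table()] (categorical; apply
#'   [discretize()] / [apply_bin_edges()] beforehand when features are
#'   numeric).
#' @param model one of [twd_models()].
#' @param test an [information_table()] or a data.frame of attribute values
#'   sharing the training schema.
#' @param concept_label decision value defining the concept.
#' @param attrs attribute subset to use (default: all training attributes).
#' @param ... passed to the threshold learner.
#' @return Character vector of decisions (`accept`/`reject`/`defer`), one
#'   per test object.
#' @export
classify_holdout <- function(train_table, model, test, concept_label,
                             attrs = attributes_of(train_table), ...) {
  .check_model(model)
  fit <- .fit_twd(train_table, concept_label, model, attrs, ...)
  test_tab <- if (inherits(test, "information_table")) test else
    information_table(as.data.frame(test), decision = rep("?", nrow(test)))
  missing_attr <- setdiff(attrs, names(test_tab$data))
  if (length(missing_attr))
    stop("test records lack attribute(s): ",
         paste(missing_attr, collapse = ", "), call. = FALSE)
  sig <- .signatures(test_tab, attrs)
  region <- fit$region[match(sig, fit$signature)]
  region[is.na(region)] <- "BND"
  unname(c(POS = "accept", NEG = "reject", BND = "defer")[region])
}

#' Most frequent decision labels
#'
#' @param table an [information_table()].
#' @param n number of labels to return.
#' @return Labels sorted by frequency, ties broken lexicographically.
#' @export
top_concept_labels <- function(table, n = 5) {
  stopifnot(inherits(table, "information_table"))
  freq <- table(table$decision)
  lab <- names(freq)[order(-as.integer(freq), names(freq))]
  utils::head(lab, n)
}

#' Stratified k-fold cross-validation of a three-way model
#'
#' Folds are stratified by decision label from the given seed.  Per fold the
#' model is fitted on the training part (discretization edges, thresholds
#' and regions all learned on training data only) and the held-out objects
#' are classified with [classify_holdout()].  Test accuracy counts only
#' decided objects (mirroring the accuracy denominator) and test generality
#' is the decided fraction.  Folds in which no test object is decided
#' contribute an undefined accuracy and are excluded from the accuracy mean,
#' with their count reported.
#'
#' @param table an [information_table()].
#' @param concept_label decision value defining the concept.
#' @param model one of [twd_models()].
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the fold assignment.
#' @param attrs attribute subset to use (default: all).
#' @param policy,bins discretization settings for numeric attributes.
#' @param ... passed to the threshold learner.
#' @return Object of class `cv_report`: per-fold data.frame plus
#'   `mean_accuracy`, `sd_accuracy`, `mean_generality`, `sd_generality`,
#'   `undefined_folds`.
#' @export
cross_validate <- function(table, concept_label, model, k = 10, seed = 1,
                           attrs = attributes_of(table),
                           policy = "equal_frequency", bins = 5, ...) {
  stopifnot(inherits(table, "information_table"))
  .check_model(model)
  n <- length(table$ids)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k objects", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  for (lab in unique(table$decision)) {
    idx <- which(table$decision == lab)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  has_numeric <- any(vapply(table$data[attrs], is.numeric, TRUE))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    if (!any(fold == f)) next   # possible when a stratum is tiny
    train <- subset_objects(table, table$ids[fold != f])
    test <- subset_objects(table, table$ids[fold == f])
    if (has_numeric) {
      train <- discretize(train, policy, bins)
      test <- apply_bin_edges(test, train$bin_edges)
    }
    dec <- classify_holdout(train, model, test, concept_label,
                            attrs = attrs, ...)
    decided <- dec != "defer"
    truth <- test$decision == concept_label
    correct <- (dec == "accept" & truth) | (dec == "reject" & !truth)
    rows[[f]] <- data.frame(
      fold = f, n_test = length(dec), decided = sum(decided),
      accuracy = if (any(decided)) sum(correct[decided]) / sum(decided)
                 else NA_real_,
      generality = mean(decided))
  }
  per_fold <- do.call(rbind, rows)
  acc <- per_fold$accuracy[!is.na(per_fold$accuracy)]
  structure(list(
    model = model, concept_label = concept_label, k = k, seed = seed,
    per_fold = per_fold,
    mean_accuracy = if (length(acc)) mean(acc) else NA_real_,
    sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else NA_real_,
    mean_generality = mean(per_fold$generality),
    sd_generality = stats::sd(per_fold$generality),
    undefined_folds = sum(is.na(per_fold$accuracy))),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV, model %s, concept '%s' (seed %d)\n", x$k, x$model,
    x$concept_label, x$seed))
  cat(sprintf("  accuracy  : %.4f (sd %.4f, %d undefined fold(s))\n",
              x$mean_accuracy, x$sd_accuracy, x$undefined_folds))
  cat(sprintf("  generality: %.4f (sd %.4f)\n",
              x$mean_generality, x$sd_generality))
  invisible(x)
}
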