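# Floating-point guard for threshold comparisons.  Region membership uses
# the exact inequalities P >= alpha, P <= beta; the guard only absorbs
# representation error when block probabilities are computed in doubles.
.TOL <- 1e-12

#' Construct a valid (alpha, beta) threshold pair
#'
#' Probabilistic regions compare the conditional probability P(C|\[x\]) of
#' each equivalence class against two cutoffs.  To keep the three regions
#' disjoint the pair must satisfy 0 <= beta < alpha <= 1; beta = alpha is
#' rejected at construction.
#'
#' @param alpha acceptance threshold.
#' @param beta rejection threshold.
#' @return Object of class `threshold_pair`.
#' @export
threshold_pair <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L)
    stop("alpha and beta must be single numbers", call. = FALSE)
  if (!(beta >= 0 && beta < alpha && alpha <= 1))
    stop("thresholds must satisfy 0 <= beta < alpha <= 1 (got alpha = ",
         alpha, ", beta = ", beta, ")", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("(alpha, beta) = (%g, %g)\n", x$alpha, x$beta))
  invisible(x)
}

.new_tripartition <- function(pos, neg, bnd, thresholds, concept_label,
                              universe, block_probs = NULL) {
  structure(list(pos = pos, neg = neg, bnd = bnd,
                 thresholds = thresholds, concept_label = concept_label,
                 universe = universe, block_probs = block_probs),
            class = "tripartition")
}

#' @export
print.tripartition <- function(x, ...) {
  thr <- if (identical(x$thresholds, "pawlak")) "Pawlak"
         else sprintf("(alpha, beta) = (%g, %g)",
                      x$thresholds$alpha, x$thresholds$beta)
  cat("Tri-partition for concept '", x$concept_label, "' [", thr, "]\n",
      sep = "")
  cat(sprintf("  POS (accept): %d  NEG (reject): %d  BND (defer): %d\n",
              length(x$pos), length(x$neg), length(x$bnd)))
  invisible(x)
}

.check_same_universe <- function(partition, concept) {
  if (!setequal(partition$universe, concept$universe))
    stop("partition and concept are over different universes", call. = FALSE)
  invisible(TRUE)
}

#' Pawlak three-way regions
#'
#' The classical rough-set trisection: a block goes to the positive region
#' when it is fully contained in the concept (\[x\] subset of C), to the
#' negative region when it is disjoint from it, and to the boundary
#' otherwise.  The lower approximation is POS and the upper approximation
#' POS union BND.
#'
#' @param partition a [compute_partition()] result.
#' @param concept a [concept_from_decision()] result over the same universe.
#' @return Object of class `tripartition` with fields `pos`, `neg`, `bnd`
#'   (character vectors of object ids), `thresholds = "pawlak"` and
#'   `concept_label`.
#' @examples
#' tab <- table1_fixture()
#' pawlak_regions(compute_partition(tab, "Localization"),
#'                concept_from_decision(tab, "Yes"))
#' @export
pawlak_regions <- function(partition, concept) {
  stopifnot(inherits(partition, "partition"), inherits(concept, "concept"))
  .check_same_universe(partition, concept)
  pos <- character(0); neg <- character(0); bnd <- character(0)
  probs <- numeric(0)
  for (b in partition$blocks) {
    k <- sum(b$members %in% concept$members)
    probs <- c(probs, k / length(b$members))
    if (k == length(b$members)) pos <- c(pos, b$members)
    else if (k == 0L) neg <- c(neg, b$members)
    else bnd <- c(bnd, b$members)
  }
  .new_tripartition(pos, neg, bnd, "pawlak", concept$label,
                    partition$universe, probs)
}

#' Probabilistic (alpha, beta) three-way regions
#'
#' Graded version of [pawlak_regions()]: a block joins the positive region
#' when P(C|\[x\]) >= alpha, the negative region when P(C|\[x\]) <= beta,
#' and the boundary when beta < P(C|\[x\]) < alpha.  Ties at a threshold
#' therefore go to the decisive region.  At (alpha, beta) = (1, 0) this
#' reduces exactly to the Pawlak trisection.
#'
#' @inheritParams pawlak_regions
#' @param thresholds a [threshold_pair()].
#' @return A `tripartition`; see [pawlak_regions()].
#' @export
probabilistic_regions <- function(partition, concept, thresholds) {
  stopifnot(inherits(partition, "partition"), inherits(concept, "concept"))
  if (!inherits(thresholds, "threshold_pair"))
    thresholds <- threshold_pair(thresholds[[1L]], thresholds[[2L]])
  .check_same_universe(partition, concept)
  pos <- character(0); neg <- character(0); bnd <- character(0)
  probs <- numeric(0)
  for (b in partition$blocks) {
    p <- sum(b$members %in% concept$members) / length(b$members)
    probs <- c(probs, p)
    if (p >= thresholds$alpha - .TOL) pos <- c(pos, b$members)
    else if (p <= thresholds$beta + .TOL) neg <- c(neg, b$members)
    else bnd <- c(bnd, b$members)
  }
  .new_tripartition(pos, neg, bnd, thresholds, concept$label,
                    partition$universe, probs)
}

#' Three-way decision for a single object
#'
#' Accept an object as belonging to the concept when it lies in the positive
#' region, reject it in the negative region, defer it in the boundary.
#'
#' @param tri a `tripartition`.
#' @param object_id an object identifier in the universe.
#' @return `"accept"`, `"reject"` or `"defer"`.
#' @export
decide <- function(tri, object_id) {
  stopifnot(inherits(tri, "tripartition"))
  if (!object_id %in% tri$universe)
    stop("unknown object: ", object_id, call. = FALSE)
  if (object_id %in% tri$pos) "accept"
  else if (object_id %in% tri$neg) "reject"
  else "defer"
}

#' Region assignment as a data frame
#'
#' @param tri a `tripartition`.
#' @return data.frame with columns `object_id`, `region` (POS/NEG/BND) and
#'   `decision` (accept/reject/defer), one row per object in universe order.
#' @export
region_table <- function(tri) {
  stopifnot(inherits(tri, "tripartition"))
  region <- ifelse(tri$universe %in% tri$pos, "POS",
            ifelse(tri$universe %in% tri$neg, "NEG", "BND"))
  decision <- c(POS = "accept", NEG = "reject", BND = "defer")[region]
  data.frame(object_id = tri$universe, region = region,
             decision = unname(decision), stringsAsFactors = FALSE)
}

#' Write a region assignment to a TSV file
#'
#' One row per object: id, region label (POS/NEG/BND) and decision
#' (accept/reject/defer).  [read_regions()] restores the assignment.
#'
#' @param tri a `tripartition`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_regions <- function(tri, path) {
  df <- region_table(tri)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write regions to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a region assignment written by [write_regions()]
#'
#' @param path file to read.
#' @return data.frame with columns `object_id`, `region`, `decision`.
#' @export
read_regions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", stringsAsFactors = FALSE)
}
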