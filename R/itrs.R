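# Information-theoretic threshold learning (ITRS).
#
# The overall uncertainty of a trisection is
#   Delta(alpha, beta) = Delta_P + Delta_N + Delta_B,
# where Delta_R = P(R) * delta_R weighs the conditional uncertainty
# delta_R of region R by its probability P(R) = |R| / |U|.  delta_R is the
# Shannon entropy (base 2, bits) or the Gini coefficient of the two-way
# composition {P(C|R), P(C^c|R)}.  ITRS chooses thresholds minimizing Delta.

# per-composition uncertainty; 0 log 0 = 0 by convention, empty regions
# (p = NaN) contribute 0 so Delta stays continuous in region size
.delta_measure <- function(p, measure) {
  out <- numeric(length(p))
  ok <- !is.nan(p) & p > 0 & p < 1
  if (measure == "shannon") {
    q <- p[ok]
    out[ok] <- -q * log2(q) - (1 - q) * log2(1 - q)
  } else {
    q <- p[ok]
    out[ok] <- 1 - q^2 - (1 - q)^2
  }
  out
}

# Vectorized Delta over many (alpha, beta) pairs for one block profile.
# probs: P(C|[x]) per block; weights: |[x]| / |U| per block.
.delta_pairs <- function(probs, weights, alphas, betas, measure) {
  pos <- outer(probs, alphas, function(p, a) p >= a - .TOL)
  neg <- outer(probs, betas, function(p, b) p <= b + .TOL) & !pos
  bnd <- !pos & !neg
  wp <- weights * probs
  region_delta <- function(mask) {
    pr <- colSums(weights * mask)
    pc <- colSums(wp * mask) / pr           # NaN when region empty
    pr * .delta_measure(pc, measure)        # 0 * anything finite; pr=0 -> 0
  }
  region_delta(pos) + region_delta(neg) + region_delta(bnd)
}

.report_from_sets <- function(pos, neg, bnd, concept, measure) {
  u <- length(pos) + length(neg) + length(bnd)
  comp <- function(r) {
    if (!length(r)) return(NaN)
    sum(r %in% concept$members) / length(r)
  }
  p_r <- c(POS = length(pos), NEG = length(neg), BND = length(bnd)) / u
  p_c <- c(POS = comp(pos), NEG = comp(neg), BND = comp(bnd))
  delta <- .delta_measure(p_c, measure)
  names(delta) <- names(p_c)
  weighted <- p_r * delta
  structure(list(measure = measure, region_probs = p_r,
                 concept_given_region = p_c, delta = delta,
                 weighted = weighted, total = sum(weighted)),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("Region uncertainty (", x$measure, ")\n", sep = "")
  df <- data.frame(`P(R)` = x$region_probs,
                   `P(C|R)` = x$concept_given_region,
                   delta = x$delta, weighted = x$weighted,
                   check.names = FALSE)
  print(round(df, 4))
  cat(sprintf("Total Delta = %.4f\n", x$total))
  invisible(x)
}

#' Uncertainty of the three regions
#'
#' Computes the per-region conditional uncertainties delta_P, delta_N,
#' delta_B of the concept-versus-complement composition (Shannon entropy in
#' bits, or Gini), the region probabilities P(R) = |R|/|U|, the weighted
#' terms Delta_R = P(R) delta_R, and their sum Delta.  An empty region has
#' P(R) = 0 and its delta is defined as 0.
#'
#' @param tri a `tripartition`.
#' @param concept a [concept_from_decision()] result over the same universe.
#' @param measure `"shannon"` or `"gini"`.
#' @return Object of class `uncertainty_report` with fields `measure`,
#'   `region_probs`, `concept_given_region`, `delta`, `weighted`, `total`.
#' @examples
#' tab <- table1_fixture()
#' tri <- pawlak_regions(
#'   compute_partition(tab, c("Localization", "Interacting proteins")),
#'   concept_from_decision(tab, "Yes")
#' )
#' region_uncertainty(tri, concept_from_decision(tab, "Yes"), "shannon")
#' @export
region_uncertainty <- function(tri, concept, measure = c("shannon", "gini")) {
  stopifnot(inherits(tri, "tripartition"), inherits(concept, "concept"))
  measure <- match.arg(measure)
  if (!length(tri$universe)) stop("empty universe", call. = FALSE)
  if (!setequal(tri$universe, concept$universe))
    stop("tri-partition and concept are over different universes",
         call. = FALSE)
  .report_from_sets(tri$pos, tri$neg, tri$bnd, concept, measure)
}

#' Learn (alpha, beta) by minimizing region uncertainty (ITRS)
#'
#' Searches for the threshold pair minimizing the total uncertainty
#' Delta(alpha, beta).  Because a trisection only changes when a threshold
#' crosses a block probability, Delta is piecewise constant and the set of
#' distinct block probabilities augmented with \{0, 1\} is a sufficient
#' candidate grid (`search = "candidate_grid"`, the default, exact).  A
#' uniform dense grid is retained for cross-checking.  Ties are broken
#' toward the most conservative pair: largest alpha, then smallest beta, so
#' a fully consistent table returns the Pawlak thresholds (1, 0).
#'
#' @param partition a [compute_partition()] result.
#' @param concept a [concept_from_decision()] result.
#' @param measure `"shannon"` or `"gini"`.
#' @param search `"candidate_grid"` or `"dense_grid"`.
#' @param resolution step of the dense grid (default 0.01).
#' @return Object of class `itrs_result`: `thresholds` (a
#'   [threshold_pair()]), `report` (the [region_uncertainty()] report at the
#'   optimum), `candidates_examined`, `tie_set` (data.frame of all pairs
#'   attaining the minimum) and a `degenerate` flag.
#' @export
itrs_learn_thresholds <- function(partition, concept,
                                  measure = c("shannon", "gini"),
                                  search = c("candidate_grid", "dense_grid"),
                                  resolution = 0.01) {
  stopifnot(inherits(partition, "partition"), inherits(concept, "concept"))
  measure <- match.arg(measure)
  search <- match.arg(search)
  .check_same_universe(partition, concept)
  if (!length(partition$blocks)) stop("empty partition", call. = FALSE)
  sizes <- vapply(partition$blocks, function(b) length(b$members), 1L)
  probs <- vapply(partition$blocks,
                  function(b) sum(b$members %in% concept$members) /
                    length(b$members), 1)
  weights <- sizes / sum(sizes)
  vals <- if (search == "candidate_grid") {
    v <- sort(unique(c(0, 1, probs)))
    v[c(TRUE, diff(v) > .TOL)]   # collapse float-identical candidates
  } else {
    seq(0, 1, by = resolution)
  }
  grid <- expand.grid(beta = vals, alpha = vals)
  grid <- grid[grid$beta < grid$alpha - .TOL, c("alpha", "beta")]
  degenerate <- nrow(grid) == 0L
  if (degenerate) grid <- data.frame(alpha = 1, beta = 0)
  total <- .delta_pairs(probs, weights, grid$alpha, grid$beta, measure)
  best <- min(total)
  tie <- grid[total <= best + 1e-12, , drop = FALSE]
  # most conservative minimizer: largest alpha, then smallest beta
  tie <- tie[order(-tie$alpha, tie$beta), , drop = FALSE]
  thr <- threshold_pair(tie$alpha[1L], tie$beta[1L])
  tri <- probabilistic_regions(partition, concept, thr)
  structure(list(thresholds = thr,
                 report = region_uncertainty(tri, concept, measure),
                 candidates_examined = nrow(grid),
                 tie_set = tie, measure = measure, search = search,
                 degenerate = degenerate),
            class = "itrs_result")
}

#' @export
print.itrs_result <- function(x, ...) {
  cat("ITRS (", x$measure, ", ", x$search, "): ", sep = "")
  print(x$thresholds)
  cat(sprintf("Delta = %.6f over %d candidate pairs (%d tied)\n",
              x$report$total, x$candidates_examined, nrow(x$tie_set)))
  invisible(x)
}
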