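# Game-theoretic threshold learning (GTRS).
#
# Two players perturb the thresholds of a probabilistic trisection: player 1
# lowers alpha, player 2 raises beta.  Payoffs score the regions that result
# from the jointly perturbed thresholds; repeated games solved at a
# pure-strategy Nash equilibrium move (alpha, beta) away from the Pawlak
# point (1, 0) until no profitable joint move remains.
#
# The payoff forms used by the three variants are this package's own
# definitions (see the methods vignette):
#   gtrs_e / gtrs_g : player I (immediate) gets 1 minus the size-weighted
#     average uncertainty of POS u NEG; player D (deferred) gets
#     1 - delta_B.  Uncertainty is Shannon (gtrs_e) or Gini (gtrs_g).
#   gtrs_ag : player A gets the accuracy, player G the generality, of the
#     trisection at the perturbed thresholds.

#' Uncertainty-based payoffs for the immediate and deferred players
#'
#' @param partition a [compute_partition()] result.
#' @param concept a [concept_from_decision()] result.
#' @param thresholds a [threshold_pair()].
#' @param measure `"shannon"` or `"gini"`.
#' @return Numeric pair `c(u_I, u_D)`, both in \[0, 1\]: u_I = 1 - average
#'   uncertainty of the immediate (POS u NEG) regions, 0 when both are
#'   empty; u_D = 1 - delta_B, 1 when the boundary is empty.
#' @export
uncertainty_payoffs <- function(partition, concept, thresholds,
                                measure = c("shannon", "gini")) {
  measure <- match.arg(measure)
  tri <- probabilistic_regions(partition, concept, thresholds)
  rep <- region_uncertainty(tri, concept, measure)
  p_imm <- rep$region_probs[["POS"]] + rep$region_probs[["NEG"]]
  u_i <- if (p_imm > 0)
    1 - (rep$weighted[["POS"]] + rep$weighted[["NEG"]]) / p_imm else 0
  u_d <- if (length(tri$bnd)) 1 - rep$delta[["BND"]] else 1
  c(u_I = u_i, u_D = u_d)
}

#' Accuracy and generality payoffs
#'
#' @inheritParams uncertainty_payoffs
#' @return Numeric pair `c(u_A, u_G)`: the accuracy and generality of the
#'   trisection at `thresholds`.  When the immediate regions are empty the
#'   accuracy is undefined and the pair is `(0, 0)` with attribute
#'   `undefined_accuracy = TRUE`.
#' @export
accuracy_generality_payoffs <- function(partition, concept, thresholds) {
  tri <- probabilistic_regions(partition, concept, thresholds)
  if (!length(tri$pos) && !length(tri$neg)) {
    out <- c(u_A = 0, u_G = 0)
    attr(out, "undefined_accuracy") <- TRUE
    return(out)
  }
  c(u_A = accuracy(tri, concept), u_G = generality(tri, concept))
}

#' Construct a two-player normal-form game
#'
#' @param u1,u2 payoff matrices for players 1 and 2; rows index player-1
#'   strategies, columns player-2 strategies.
#' @param strategies1,strategies2 optional lists describing each strategy
#'   (for threshold games: lists with `dalpha`, `dbeta`, `label`).
#' @param base_thresholds optional [threshold_pair()] the perturbations
#'   apply to.
#' @return Object of class `twd_game`.
#' @export
normal_form_game <- function(u1, u2, strategies1 = NULL, strategies2 = NULL,
                             base_thresholds = NULL) {
  u1 <- as.matrix(u1); u2 <- as.matrix(u2)
  if (!all(dim(u1) == dim(u2)))
    stop("payoff matrices must have identical dimensions", call. = FALSE)
  if (is.null(strategies1))
    strategies1 <- lapply(seq_len(nrow(u1)), function(i)
      list(dalpha = 0, dbeta = 0, label = paste0("s", i)))
  if (is.null(strategies2))
    strategies2 <- lapply(seq_len(ncol(u1)), function(j)
      list(dalpha = 0, dbeta = 0, label = paste0("s", j)))
  structure(list(players = c("player1", "player2"),
                 u1 = u1, u2 = u2,
                 strategies1 = strategies1, strategies2 = strategies2,
                 base_thresholds = base_thresholds),
            class = "twd_game")
}

#' @export
print.twd_game <- function(x, ...) {
  cat("Two-player game: ", nrow(x$u1), " x ", ncol(x$u1), " strategies\n",
      sep = "")
  lab1 <- vapply(x$strategies1, `[[`, "", "label")
  lab2 <- vapply(x$strategies2, `[[`, "", "label")
  cells <- matrix(sprintf("(%.3f, %.3f)", x$u1, x$u2),
                  nrow(x$u1), dimnames = list(lab1, lab2))
  print(cells, quote = FALSE)
  invisible(x)
}

#' Build a threshold-perturbation game
#'
#' Player 1's strategies decrease alpha by each step (plus "no change");
#' player 2's increase beta likewise.  Each profile is evaluated at the
#' jointly perturbed thresholds; profiles whose thresholds violate
#' 0 <= beta < alpha <= 1 are infeasible and receive payoff `-Inf` for both
#' players.
#'
#' @inheritParams uncertainty_payoffs
#' @param variant `"gtrs_e"`, `"gtrs_g"` (uncertainty players, Shannon /
#'   Gini) or `"gtrs_ag"` (accuracy / generality players).
#' @param base the [threshold_pair()] the perturbations apply to.
#' @param steps nonnegative step sizes (default `c(0.05, 0.10)`).
#' @return A [normal_form_game()] whose strategies record the perturbations.
#' @export
build_game <- function(partition, concept,
                       variant = c("gtrs_e", "gtrs_g", "gtrs_ag"),
                       base = threshold_pair(1, 0),
                       steps = c(0.05, 0.10)) {
  variant <- match.arg(variant)
  if (!inherits(base, "threshold_pair"))
    base <- threshold_pair(base[[1L]], base[[2L]])
  if (!length(steps) || any(steps < 0))
    stop("`steps` must be a nonempty vector of nonnegative step sizes",
         call. = FALSE)
  steps <- sort(unique(steps[steps > 0]))
  s1 <- c(list(list(dalpha = 0, dbeta = 0, label = "stay")),
          lapply(steps, function(s)
            list(dalpha = -s, dbeta = 0, label = sprintf("alpha-%g", s))))
  s2 <- c(list(list(dalpha = 0, dbeta = 0, label = "stay")),
          lapply(steps, function(s)
            list(dalpha = 0, dbeta = s, label = sprintf("beta+%g", s))))
  payoff <- function(thr) switch(variant,
    gtrs_e = uncertainty_payoffs(partition, concept, thr, "shannon"),
    gtrs_g = uncertainty_payoffs(partition, concept, thr, "gini"),
    gtrs_ag = accuracy_generality_payoffs(partition, concept, thr))
  m <- length(s1); n <- length(s2)
  u1 <- matrix(-Inf, m, n); u2 <- matrix(-Inf, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    a <- base$alpha + s1[[i]]$dalpha
    b <- base$beta + s2[[j]]$dbeta
    if (b >= 0 && a <= 1 && b < a - .TOL) {
      u <- payoff(threshold_pair(a, b))
      u1[i, j] <- u[[1L]]; u2[i, j] <- u[[2L]]
    }
  }
  normal_form_game(u1, u2, s1, s2, base)
}

#' Enumerate pure-strategy Nash equilibria
#'
#' A profile (s1, s2) is a pure-strategy Nash equilibrium when neither
#' player can improve its own payoff by a unilateral deviation; every
#' profile is checked against all deviations by direct payoff comparison.
#' Infeasible profiles (payoff `-Inf`) are never reported as equilibria.
#' Among multiple equilibria one is selected deterministically: maximal
#' payoff sum, then minimal total threshold movement, then lexicographic
#' strategy order.
#'
#' @param game a [normal_form_game()].
#' @return Object of class `equilibrium_result`: `equilibria` (data.frame
#'   with strategy indices, labels and payoffs), `selected` (row index into
#'   `equilibria`, or `NA` when none exists) and `resulting_thresholds`
#'   (the [threshold_pair()] after applying the selected profile, when the
#'   game carries base thresholds).
#' @export
find_pure_nash <- function(game) {
  stopifnot(inherits(game, "twd_game"))
  u1 <- game$u1; u2 <- game$u2
  m <- nrow(u1); n <- ncol(u1)
  col_max1 <- apply(u1, 2, max)   # best response of player 1 per column
  row_max2 <- apply(u2, 1, max)   # best response of player 2 per row
  eq <- which(u1 == rep(col_max1, each = m) &
              u2 == matrix(row_max2, m, n) &
              is.finite(u1) & is.finite(u2), arr.ind = TRUE)
  if (!nrow(eq)) {
    return(structure(list(equilibria = data.frame(), selected = NA,
                          resulting_thresholds = NULL, game = game),
                     class = "equilibrium_result"))
  }
  move <- function(i, j) abs(game$strategies1[[i]]$dalpha) +
    abs(game$strategies2[[j]]$dbeta)
  df <- data.frame(
    i = eq[, 1L], j = eq[, 2L],
    label1 = vapply(eq[, 1L], function(i) game$strategies1[[i]]$label, ""),
    label2 = vapply(eq[, 2L], function(j) game$strategies2[[j]]$label, ""),
    u1 = u1[eq], u2 = u2[eq],
    movement = mapply(move, eq[, 1L], eq[, 2L]),
    stringsAsFactors = FALSE)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  sel <- order(-(df$u1 + df$u2), df$movement, df$i, df$j)[1L]
  thr <- NULL
  if (!is.null(game$base_thresholds)) {
    b <- game$base_thresholds
    thr <- threshold_pair(b$alpha + game$strategies1[[df$i[sel]]]$dalpha,
                          b$beta + game$strategies2[[df$j[sel]]]$dbeta)
  }
  structure(list(equilibria = df, selected = sel,
                 resulting_thresholds = thr, game = game),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  if (!nrow(x$equilibria)) {
    cat("No pure-strategy Nash equilibrium\n")
    return(invisible(x))
  }
  cat(nrow(x$equilibria), "pure-strategy Nash equilibrium(a); selected:\n")
  print(x$equilibria[x$selected, ])
  invisible(x)
}

#' Learn (alpha, beta) by repeated threshold-perturbation games (GTRS)
#'
#' Starting from `alpha0`/`beta0` (default the Pawlak point (1, 0)),
#' repeatedly build the perturbation game at the current thresholds, solve
#' it at a pure Nash equilibrium, and apply the selected profile.  The loop
#' stops when (a) the selected profile is (stay, stay), (b) the selected
#' profile's payoff sum improves on the stay-profile's by less than
#' `stop_epsilon`, (c) the next thresholds would be infeasible, or (d)
#' `max_iterations` is reached.  When a game has no pure equilibrium the
#' stay profile is taken and the loop stops.  The returned thresholds always
#' satisfy 0 <= beta < alpha <= 1.
#'
#' @inheritParams build_game
#' @param alpha0,beta0 initial thresholds.
#' @param steps perturbation step sizes per game.
#' @param max_iterations cap on the number of repeated games.
#' @param stop_epsilon minimal payoff-sum improvement to keep moving.
#' @return Object of class `gtrs_result`: `thresholds` (a
#'   [threshold_pair()]), `iterations`, `stopped_by`, and `trace`
#'   (data.frame of per-iteration thresholds, selected labels and payoffs).
#' @export
gtrs_learn_thresholds <- function(partition, concept,
                                  variant = c("gtrs_e", "gtrs_g", "gtrs_ag"),
                                  alpha0 = 1, beta0 = 0,
                                  steps = c(0.05, 0.10),
                                  max_iterations = 50,
                                  stop_epsilon = 1e-6) {
  variant <- match.arg(variant)
  thr <- threshold_pair(alpha0, beta0)
  trace <- list()
  stopped_by <- "max_iterations"
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    game <- build_game(partition, concept, variant, thr, steps)
    eqr <- find_pure_nash(game)
    if (!nrow(eqr$equilibria)) {  # fallback: treat (stay, stay) as selected
      stopped_by <- "no_pure_equilibrium"
      trace[[iter]] <- data.frame(iteration = iter, alpha = thr$alpha,
                                  beta = thr$beta, label1 = "stay",
                                  label2 = "stay", u1 = game$u1[1L, 1L],
                                  u2 = game$u2[1L, 1L])
      break
    }
    sel <- eqr$equilibria[eqr$selected, ]
    trace[[iter]] <- data.frame(iteration = iter, alpha = thr$alpha,
                                beta = thr$beta, label1 = sel$label1,
                                label2 = sel$label2, u1 = sel$u1,
                                u2 = sel$u2)
    if (sel$movement == 0) { stopped_by <- "stay_profile"; break }
    stay_sum <- game$u1[1L, 1L] + game$u2[1L, 1L]
    if (!is.finite(stay_sum)) stay_sum <- -Inf
    if (sel$u1 + sel$u2 - stay_sum < stop_epsilon) {
      stopped_by <- "no_improvement"; break
    }
    if (is.null(eqr$resulting_thresholds)) {
      stopped_by <- "infeasible_next"; break
    }
    thr <- eqr$resulting_thresholds
  }
  structure(list(thresholds = thr, variant = variant, iterations = iter,
                 stopped_by = stopped_by,
                 trace = do.call(rbind, trace)),
            class = "gtrs_result")
}

#' @export
print.gtrs_result <- function(x, ...) {
  cat("GTRS (", x$variant, "), ", x$iterations, " game(s), stopped by ",
      x$stopped_by, "\n", sep = "")
  print(x$thresholds)
  invisible(x)
}
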