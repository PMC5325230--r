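tab1 <- table1_fixture()
concept1 <- concept_from_decision(tab1, "Yes")
part_t1 <- compute_partition(tab1, c("Localization", "Interacting proteins"))
part_t0 <- compute_partition(tab1, "Localization")
part_t2 <- compute_partition(tab1)

test_that("uncertainty payoffs score the immediate and deferred regions", {
  u <- uncertainty_payoffs(part_t1, concept1, threshold_pair(1, 0),
                           "shannon")
  expect_equal(u[["u_I"]], 1)                      # pure immediate regions
  expect_equal(u[["u_D"]], 1 - 0.9182958, tolerance = 1e-6)

  u2 <- uncertainty_payoffs(part_t2, concept1, threshold_pair(1, 0),
                            "shannon")
  expect_equal(unname(u2), c(1, 1))                # consistent: BND empty

  # all-boundary configuration with a half-half block: worst of both
  coin <- information_table(data.frame(x = c("a", "a")),
                            decision = c("Yes", "No"))
  u3 <- uncertainty_payoffs(compute_partition(coin, "x"),
                            concept_from_decision(coin, "Yes"),
                            threshold_pair(0.9, 0.1), "shannon")
  expect_equal(unname(u3), c(0, 0))
})

test_that("accuracy/generality payoffs evaluate Eq-style region counts", {
  ag <- accuracy_generality_payoffs(part_t1, concept1, threshold_pair(1, 0))
  expect_equal(unname(ag), c(1, 0.625))

  ag0 <- accuracy_generality_payoffs(part_t0, concept1, threshold_pair(1, 0))
  expect_equal(as.numeric(ag0), c(0, 0))
  expect_true(attr(ag0, "undefined_accuracy"))

  ag2 <- accuracy_generality_payoffs(part_t1, concept1,
                                     threshold_pair(0.3, 0.2))
  expect_equal(unname(ag2), c(0.75, 1))
})

test_that("game construction enumerates perturbation profiles", {
  g <- build_game(part_t1, concept1, "gtrs_e", threshold_pair(1, 0), 0.05)
  expect_equal(dim(g$u1), c(2L, 2L))
  expect_true(all(is.finite(g$u1)) && all(is.finite(g$u2)))

  # a joint move crossing beta over alpha is infeasible
  g2 <- build_game(part_t1, concept1, "gtrs_e", threshold_pair(0.7, 0.2),
                   0.6)
  expect_equal(g2$u1[2L, 2L], -Inf)   # alpha 0.1 < beta 0.8
  expect_equal(g2$u2[2L, 2L], -Inf)

  g3 <- build_game(part_t1, concept1, "gtrs_ag", threshold_pair(1, 0), 0.7)
  expect_equal(unname(c(g3$u1[2L, 1L], g3$u2[2L, 1L])), c(0.75, 1))
  expect_error(build_game(part_t1, concept1, "gtrs_e", threshold_pair(1, 0),
                          numeric(0)), "steps")
})

test_that("pure Nash enumeration matches direct best-response reasoning", {
  # dominant strategies (prisoner's dilemma shape): unique (2, 2)
  u1 <- matrix(c(3, 5, 0, 1), 2)
  u2 <- matrix(c(3, 0, 5, 1), 2)
  eq <- find_pure_nash(normal_form_game(u1, u2))
  expect_equal(nrow(eq$equilibria), 1L)
  expect_equal(c(eq$equilibria$i, eq$equilibria$j), c(2L, 2L))

  # constant payoffs: every profile is an equilibrium
  eqc <- find_pure_nash(normal_form_game(matrix(1, 2, 3), matrix(1, 2, 3)))
  expect_equal(nrow(eqc$equilibria), 6L)

  for (seed in 1:40) {
    set.seed(seed)
    m <- sample(2:3, 1); n <- sample(2:3, 1)
    u1 <- matrix(sample(0:5, m * n, TRUE), m)
    u2 <- matrix(sample(0:5, m * n, TRUE), m)
    eq <- find_pure_nash(normal_form_game(u1, u2))
    ora <- oracle_nash(u1, u2)
    got <- if (nrow(eq$equilibria)) as.matrix(eq$equilibria[, c("i", "j")])
           else matrix(integer(0), 0, 2)
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 unname(if (is.null(ora)) matrix(integer(0), 0, 2) else
                   ora[order(ora[, 1], ora[, 2]), , drop = FALSE]))
  }
})

test_that("repeated games keep thresholds feasible and terminate", {
  # fully consistent table: (1, 0) already maximal, stops immediately
  for (variant in c("gtrs_e", "gtrs_g", "gtrs_ag")) {
    res <- gtrs_learn_thresholds(part_t2, concept1, variant)
    expect_equal(c(res$thresholds$alpha, res$thresholds$beta), c(1, 0))
    expect_equal(res$iterations, 1L)
  }

  # max_iterations = 0 leaves the initial thresholds untouched
  res0 <- gtrs_learn_thresholds(part_t1, concept1, "gtrs_e",
                                alpha0 = 0.8, beta0 = 0.1,
                                max_iterations = 0)
  expect_equal(c(res0$thresholds$alpha, res0$thresholds$beta), c(0.8, 0.1))

  for (variant in c("gtrs_e", "gtrs_g", "gtrs_ag")) for (seed in 1:5) {
    tabr <- random_table(seed, n_objects = 30, n_attrs = 2)
    conr <- concept_from_decision(tabr, "Yes")
    res <- gtrs_learn_thresholds(compute_partition(tabr), conr, variant,
                                 max_iterations = 30)
    expect_true(res$thresholds$beta >= 0)
    expect_true(res$thresholds$beta < res$thresholds$alpha)
    expect_true(res$thresholds$alpha <= 1)
    expect_lte(res$iterations, 30L)
  }
})

test_that("the learning loop replays an independently scripted simulation", {
  steps <- c(0.05, 0.10)
  replay <- function(partition, concept, max_iter = 50) {
    thr <- c(1, 0)
    for (it in seq_len(max_iter)) {
      moves1 <- c(0, -steps); moves2 <- c(0, steps)
      u1 <- matrix(-Inf, 3, 3); u2 <- matrix(-Inf, 3, 3)
      for (i in 1:3) for (j in 1:3) {
        a <- thr[1] + moves1[i]; b <- thr[2] + moves2[j]
        if (b >= 0 && a <= 1 && b < a - 1e-12) {
          u <- uncertainty_payoffs(partition, concept,
                                   threshold_pair(a, b), "shannon")
          u1[i, j] <- u[[1]]; u2[i, j] <- u[[2]]
        }
      }
      eq <- oracle_nash(u1, u2)
      eq <- eq[is.finite(u1[eq]) & is.finite(u2[eq]), , drop = FALSE]
      if (!nrow(eq)) break
      sums <- u1[eq] + u2[eq]
      move <- abs(moves1[eq[, 1]]) + abs(moves2[eq[, 2]])
      sel <- order(-sums, move, eq[, 1], eq[, 2])[1]
      i <- eq[sel, 1]; j <- eq[sel, 2]
      if (move[sel] == 0) break
      if (u1[i, j] + u2[i, j] - (u1[1, 1] + u2[1, 1]) < 1e-6) break
      thr <- c(thr[1] + moves1[i], thr[2] + moves2[j])
    }
    thr
  }
  for (pc in list(list(part_t1, concept1),
                  list(compute_partition(random_table(3, 40, 2)),
                       concept_from_decision(random_table(3, 40, 2),
                                             "Yes")))) {
    got <- gtrs_learn_thresholds(pc[[1]], pc[[2]], "gtrs_e", steps = steps,
                                 max_iterations = 50)
    want <- replay(pc[[1]], pc[[2]])
    expect_equal(c(got$thresholds$alpha, got$thresholds$beta), want)
  }
})

test_that("generality payoff grows as the immediate regions grow", {
  part <- compute_partition(random_table(11, 40, 2))
  concept <- concept_from_decision(random_table(11, 40, 2), "Yes")
  gens <- sapply(list(c(1, 0), c(0.8, 0.1), c(0.6, 0.3), c(0.5, 0.4)),
                 function(th) accuracy_generality_payoffs(
                   part, concept, threshold_pair(th[1], th[2]))[["u_G"]])
  expect_true(all(diff(gens) >= 0))
})
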