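# Shared fixtures and independent oracles for the test suite.

# random categorical information table with a binary decision
random_table <- function(seed, n_objects = 20, n_attrs = 3, levels = 3) {
  set.seed(seed)
  data <- as.data.frame(
    lapply(seq_len(n_attrs), function(a)
      sample(paste0("v", seq_len(levels)), n_objects, replace = TRUE)),
    col.names = paste0("A", seq_len(n_attrs)))
  information_table(data,
                    decision = sample(c("Yes", "No"), n_objects,
                                      replace = TRUE, prob = c(0.4, 0.6)))
}

# block profile (P(C|[x]) and |[x]|/|U|) of a partition w.r.t. a concept
block_profile <- function(partition, concept) {
  sizes <- vapply(partition$blocks, function(b) length(b$members), 1L)
  probs <- vapply(partition$blocks, function(b)
    sum(b$members %in% concept$members) / length(b$members), 1)
  list(probs = probs, weights = sizes / sum(sizes))
}

# independent evaluation of the total region uncertainty at one (alpha,
# beta) pair: plain sums over blocks, no shared code with the package
oracle_delta <- function(probs, weights, alpha, beta, measure) {
  ent <- function(p) {
    if (is.nan(p) || p <= 0 || p >= 1) return(0)
    if (measure == "shannon") -p * log2(p) - (1 - p) * log2(1 - p)
    else 1 - p^2 - (1 - p)^2
  }
  pos <- probs >= alpha - 1e-12
  neg <- !pos & probs <= beta + 1e-12
  bnd <- !pos & !neg
  total <- 0
  for (mask in list(pos, neg, bnd)) {
    pr <- sum(weights[mask])
    if (pr > 0) {
      pc <- sum(weights[mask] * probs[mask]) / pr
      total <- total + pr * ent(pc)
    }
  }
  total
}

# brute-force minimum of Delta over a uniform (alpha, beta) grid
oracle_dense_min <- function(probs, weights, measure, step = 0.01) {
  vals <- seq(0, 1, by = step)
  best <- Inf
  for (a in vals) for (b in vals) {
    if (b >= a - 1e-12) next
    d <- oracle_delta(probs, weights, a, b, measure)
    if (d < best) best <- d
  }
  best
}

# independent pure-strategy Nash enumeration: direct double loop over
# profiles and unilateral deviations
oracle_nash <- function(u1, u2) {
  m <- nrow(u1); n <- ncol(u1)
  out <- NULL
  for (i in seq_len(m)) for (j in seq_len(n)) {
    stable <- TRUE
    for (i2 in seq_len(m)) if (u1[i2, j] > u1[i, j]) stable <- FALSE
    for (j2 in seq_len(n)) if (u2[i, j2] > u2[i, j]) stable <- FALSE
    if (stable) out <- rbind(out, c(i, j))
  }
  out
}

# write the 8-protein demonstration table as a CSV with an id column
write_fixture_csv <- function(path) {
  tab <- table1_fixture()
  df <- cbind(data.frame(id = tab$ids), tab$data, Function = tab$decision)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# region sets of the demonstration table at its three stages
table2_expected <- list(
  t0 = list(pos = character(0), neg = character(0),
            bnd = paste0("O", 1:8)),
  t1 = list(pos = c("O3", "O6"), neg = c("O4", "O5", "O7"),
            bnd = c("O1", "O2", "O8")),
  t2 = list(pos = c("O1", "O3", "O6"),
            neg = c("O2", "O4", "O5", "O7", "O8"), bnd = character(0))
)

expect_same_sets <- function(tri, expected) {
  expect_setequal(tri$pos, expected$pos)
  expect_setequal(tri$neg, expected$neg)
  expect_setequal(tri$bnd, expected$bnd)
}
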