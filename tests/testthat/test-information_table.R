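test_that("delimited round trip preserves the table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  tab <- read_information_table(path, decision_col = "Function",
                                id_col = "id")
  ref <- table1_fixture()
  expect_equal(tab$ids, ref$ids)
  expect_equal(names(tab$data), names(ref$data))
  expect_equal(tab$data, ref$data)
  expect_equal(tab$decision, ref$decision)

  # minimal 3-line file: header + 2 rows
  mini <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Loc,Dom,Function", "M,0,Yes", "C,1,No"), mini)
  small <- read_information_table(mini, decision_col = "Function")
  expect_equal(dim(small), c(2L, 2L))
  expect_true(is.numeric(small$data$Dom))
})

test_that("loading rejects malformed tables with informative errors", {
  mini <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,Loc,Dom,Function", "O1,M,0,Yes", "O2,C,,No"), mini)
  expect_error(read_information_table(mini, "Function", id_col = "id"),
               "O2.*Dom|Dom.*O2")
  writeLines(c("id,Loc,Function", "O1,M,Yes", "O1,C,No"), mini)
  expect_error(read_information_table(mini, "Function", id_col = "id"),
               "duplicate")
  writeLines(c("id,Loc,Function", "O1,M,Yes"), mini)
  expect_error(read_information_table(mini, "Fn", id_col = "id"),
               "decision column")
  expect_error(information_table(data.frame(Function. = 1),
                                 decision = "x", decision_name = "Function."),
               "attributes")
})

test_that("discretization bins numeric attributes and persists its edges", {
  tab <- information_table(data.frame(x = c(1, 2, 3, 4, 5, 6)),
                           decision = rep(c("Yes", "No"), 3))
  eq_freq <- discretize(tab, "equal_frequency", bins = 2)
  expect_equal(eq_freq$data$x, c("b1", "b1", "b1", "b2", "b2", "b2"))

  tab2 <- information_table(data.frame(x = c(0, 0, 10)),
                            decision = c("Yes", "No", "No"))
  eq_w <- discretize(tab2, "equal_width", bins = 2)
  expect_equal(eq_w$data$x, c("b1", "b1", "b2"))

  # train-derived edges clamp held-out values to the outer bins
  held_out <- information_table(data.frame(x = c(-5, 100)),
                                decision = c("Yes", "No"))
  applied <- apply_bin_edges(held_out, eq_w$bin_edges)
  expect_equal(applied$data$x, c("b1", "b2"))

  # constant column under equal frequency: one bin, no error
  const <- information_table(data.frame(x = rep(3, 4)),
                             decision = rep("Yes", 4))
  expect_equal(unique(discretize(const, "equal_frequency", 5)$data$x), "b1")
  expect_error(discretize(tab, "equal_frequency", bins = 0), "bins")
})

test_that("attribute restriction preserves objects and order", {
  tab <- table1_fixture()
  r1 <- restrict_attributes(tab, "Localization")
  expect_equal(dim(r1), c(8L, 1L))
  expect_equal(r1$decision, tab$decision)
  expect_equal(restrict_attributes(tab, attributes_of(tab))$data, tab$data)
  r0 <- restrict_attributes(tab, character(0))
  expect_equal(ncol(r0$data), 0L)
  expect_length(compute_partition(r0, character(0))$blocks, 1L)
  expect_error(restrict_attributes(tab, "Nope"), "unknown attribute")
})

test_that("equivalence-class partitioning groups indiscernible objects", {
  tab <- table1_fixture()
  p_loc <- compute_partition(tab, "Localization")
  members <- lapply(p_loc$blocks, `[[`, "members")
  expect_length(members, 2L)
  expect_true(any(vapply(members, setequal, TRUE, c("O1", "O2", "O8"))))
  expect_true(any(vapply(members, setequal, TRUE,
                         c("O3", "O4", "O5", "O6", "O7"))))

  p_li <- compute_partition(tab, c("Localization", "Interacting proteins"))
  members <- lapply(p_li$blocks, `[[`, "members")
  expect_length(members, 4L)
  for (blk in list(c("O1", "O2", "O8"), "O3", c("O4", "O5", "O7"), "O6"))
    expect_true(any(vapply(members, setequal, TRUE, blk)))

  distinct <- information_table(data.frame(x = paste0("v", 1:5)),
                                decision = rep("Yes", 5))
  expect_length(compute_partition(distinct, "x")$blocks, 5L)
})

test_that("concept extraction reads the decision column", {
  tab <- table1_fixture()
  expect_setequal(concept_from_decision(tab, "Yes")$members,
                  c("O1", "O3", "O6"))
  expect_setequal(concept_from_decision(tab, "No")$members,
                  c("O2", "O4", "O5", "O7", "O8"))
  expect_warning(empty <- concept_from_decision(tab, "Maybe"), "empty")
  expect_length(empty$members, 0L)
})

test_that("conditional probability counts the block-concept overlap", {
  tab <- table1_fixture()
  concept <- concept_from_decision(tab, "Yes")
  expect_equal(conditional_probability(c("O1", "O2", "O8"), concept), 1 / 3)
  expect_equal(conditional_probability(c("O1", "O3"), concept), 1)
  expect_equal(conditional_probability(c("O4", "O5"), concept), 0)
  expect_error(conditional_probability(character(0), concept), "empty")
})

test_that("partitions are true partitions with the expected structure", {
  for (seed in 1:20) {
    tab <- random_table(seed, n_objects = 15 + seed, n_attrs = 4)
    attrs <- sample(attributes_of(tab), sample(0:4, 1))
    part <- compute_partition(tab, attrs)
    members <- unlist(lapply(part$blocks, `[[`, "members"))
    expect_equal(sort(members), sort(tab$ids))       # cover, no overlap
    expect_equal(anyDuplicated(members), 0L)

    # refinement monotonicity: finer attribute set splits blocks
    sub <- if (length(attrs)) sample(attrs, sample(seq_along(attrs), 1)) else
      character(0)
    coarse <- compute_partition(tab, sub)
    for (b in part$blocks) {
      parents <- vapply(coarse$blocks,
                        function(cb) all(b$members %in% cb$members), TRUE)
      expect_equal(sum(parents), 1L)
    }

    # concept-mass conservation
    concept <- concept_from_decision(tab, "Yes")
    mass <- sum(vapply(part$blocks, function(b)
      length(b$members) * conditional_probability(b, concept), 1))
    expect_equal(mass, length(concept$members))
  }
})

test_that("partitioning is invariant to row order", {
  tab <- random_table(99, n_objects = 25)
  shuffled <- subset_objects(tab, sample(tab$ids))
  p1 <- compute_partition(tab)
  p2 <- compute_partition(shuffled)
  sig1 <- vapply(p1$blocks, function(b) paste(sort(b$members),
                                              collapse = ","), "")
  sig2 <- vapply(p2$blocks, function(b) paste(sort(b$members),
                                              collapse = ","), "")
  expect_setequal(sig1, sig2)
})
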