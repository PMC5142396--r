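test_that("replicate aggregation gives mean and sample SD", {
  expect_equal(aggregate_replicates(c(5, 5, 5)), list(mean = 5, sd = 0, n = 3L))
  agg <- aggregate_replicates(c(4, 6))
  expect_equal(agg$mean, 5)
  expect_equal(agg$sd, sqrt(2))
  expect_equal(aggregate_replicates(7)$sd, 0)
  expect_error(aggregate_replicates(numeric(0)), "at least one")

  set.seed(2)
  x <- rnorm(400, mean = 3, sd = 0.6)
  est <- aggregate_replicates(x)
  expect_lt(abs(est$mean - 3), 3 * 0.6 / sqrt(400))
  expect_lt(abs(est$sd - 0.6), 3 * 0.6 / sqrt(2 * 399))
})

test_that("max-normalization reproduces the fixture's anchor rows", {
  rec <- normalize_by_max(table1_records("C_glutamicum"))
  expect_equal(rec$relative_activity_pct[rec$sp_id == "Epr"][1], 100.0)
  expect_equal(rec$relative_activity_pct[rec$sp_id == "Vpr"], 80.2,
               tolerance = 0.1 / 80.2)
  expect_equal(rec$relative_activity_pct[rec$sp_id == "LipB"], 70.2,
               tolerance = 0.1 / 70.2)
})

test_that("normalization is scale-invariant, idempotent and per host", {
  rec <- table1_records("C_glutamicum")
  norm1 <- normalize_by_max(rec)
  scaled <- rec
  scaled$mean_activity <- scaled$mean_activity * 3.7
  expect_equal(normalize_by_max(scaled)$relative_activity_pct,
               norm1$relative_activity_pct)
  # idempotence: renormalizing the normalized series changes nothing
  again <- norm1
  again$mean_activity <- again$relative_activity_pct
  expect_equal(normalize_by_max(again)$relative_activity_pct,
               norm1$relative_activity_pct)
  # each host series is scaled by its own maximum
  both <- rbind(table1_records("C_glutamicum"), table1_records("B_subtilis"))
  nb <- normalize_by_max(both)
  for (h in unique(nb$host)) {
    expect_equal(max(nb$relative_activity_pct[nb$host == h]), 100.0)
  }
  zero <- data.frame(sp_id = "x", host = "H", mean_activity = 0)
  expect_error(normalize_by_max(zero), "all zero")
})

test_that("ranking is by descending activity with lexicographic ties", {
  rec <- table1_records("C_glutamicum")
  expect_equal(rank_sps(rec)$sp_id[1:3], c("Epr", "YwfM", "Bpr"))
  one <- rec[5, , drop = FALSE]
  expect_identical(rank_sps(one), one)
  fwd <- data.frame(sp_id = letters[1:4], mean_activity = c(4, 3, 2, 1))
  rev_in <- fwd[4:1, ]
  expect_equal(rank_sps(rev_in)$sp_id, fwd$sp_id)
  ties <- data.frame(sp_id = c("b", "a"), mean_activity = c(1, 1))
  expect_equal(rank_sps(ties)$sp_id, c("a", "b"))
})

test_that("panel classification calls clear phenotypes and reports ambiguity", {
  panel <- fig2_like_panel()
  # a clone at the strongest secreter's mean is called uniquely
  top <- classify_clone(5.0, panel, k_sigma = 2)
  expect_identical(top$assigned, "NprE")
  expect_false(top$nearest_only)
  # midway between the two overlapping weak entries: ambiguity set
  mid <- classify_clone(0.95, panel, k_sigma = 2)
  expect_setequal(mid$assigned, c("AmyE", "YwmC"))
  # far outside every interval: nearest entry, flagged
  out <- classify_clone(3.4, panel, k_sigma = 2)
  expect_true(out$nearest_only)
  expect_length(out$assigned, 1)
  # single-entry panel always returns that entry
  single <- reference_panel("NprE", 5, 0.3)
  expect_identical(classify_clone(0.1, single)$assigned, "NprE")
})

test_that("classifying each panel mean against its own panel is self-consistent", {
  panel <- fig2_like_panel()
  for (i in seq_len(nrow(panel))) {
    res <- classify_clone(panel$mean_activity[i], panel, k_sigma = 2)
    expect_true(panel$sp_id[i] %in% res$assigned)
  }
})

test_that("distinguishability groups are the closure of interval overlap", {
  panel <- fig2_like_panel()
  groups <- distinguishability_groups(panel, k_sigma = 2)
  sizes <- lengths(groups)
  expect_equal(sum(sizes > 1), 1)
  expect_setequal(groups[[which(sizes > 1)]], c("AmyE", "YwmC"))

  disjoint <- reference_panel(c("a", "b", "c"), c(1, 5, 10), c(0.1, 0.1, 0.1))
  expect_true(all(lengths(distinguishability_groups(disjoint)) == 1))

  same <- reference_panel(c("a", "b", "c"), c(1, 1, 1), c(0.1, 0.1, 0.1))
  expect_length(distinguishability_groups(same), 1)
})

test_that("well-separated panels classify synthetic clones correctly", {
  # between-SP separation >= 4 combined SDs; expect >= 95% correct at k = 2
  panel <- reference_panel(sprintf("SP%02d", 1:5),
                           mean_activity = c(0.5, 2, 4, 7, 11),
                           sd_activity = rep(0.2, 5))
  set.seed(7)
  n <- 400
  truth <- sample(seq_len(nrow(panel)), n, replace = TRUE)
  act <- rnorm(n, panel$mean_activity[truth], panel$sd_activity[truth])
  ok <- vapply(seq_len(n), function(i) {
    res <- classify_clone(act[i], panel, k_sigma = 2)
    identical(res$assigned, panel$sp_id[truth[i]])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("long activity tables aggregate per clone", {
  df <- data.frame(clone_id = rep(c("c1", "c2"), each = 3),
                   sp_id = rep(c("Epr", "Pel"), each = 3),
                   host = "H",
                   replicate = rep(1:3, 2),
                   activity = c(4, 5, 6, 1, 1, 1))
  agg <- aggregate_activity_table(df)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$mean_activity[agg$clone_id == "c1"], 5)
  expect_equal(agg$sd_activity[agg$clone_id == "c2"], 0)
  expect_equal(agg$n_replicates, c(3L, 3L))
})
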