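test_that("host pairing joins on SP identity with mean collapse of repeats", {
  a <- table1_printed_relatives("C_glutamicum")
  b <- table1_printed_relatives("B_subtilis")
  pairs <- pair_hosts(a, b)
  # SPs recovered once keep their printed relatives
  expect_equal(unlist(pairs[pairs$sp_id == "YwfM", c("rel_host_a", "rel_host_b")]),
               c(rel_host_a = 85.5, rel_host_b = 7.7))
  expect_equal(unlist(pairs[pairs$sp_id == "Pel", c("rel_host_a", "rel_host_b")]),
               c(rel_host_a = 14.5, rel_host_b = 57.2))
  # repeated SPs are collapsed by the mean of their entries
  expect_equal(pairs$rel_host_a[pairs$sp_id == "YurI"],
               mean(c(71.9, 65.6, 42.7)))
  expect_equal(nrow(pairs), length(unique(a$sp_id)))
  # per-clone mode keeps repeats
  expect_gt(nrow(pair_hosts(a, b, collapse = FALSE)), nrow(pairs))

  ident <- pair_hosts(a, a)
  expect_true(all(ident$rel_host_a == ident$rel_host_b))

  expect_error(pair_hosts(a, data.frame(sp_id = "none",
                                        relative_activity_pct = 1)),
               "shared")
})

test_that("correlations hit the exact bounds on perfectly ordered pairs", {
  up <- data.frame(sp_id = letters[1:5], rel_host_a = c(5, 20, 40, 70, 100),
                   rel_host_b = c(5, 20, 40, 70, 100))
  s <- crosshost_correlation(up)
  expect_equal(s$pearson_r, 1.0)
  expect_equal(s$spearman_rho, 1.0)
  down <- up
  down$rel_host_b <- 100 - down$rel_host_a
  s <- crosshost_correlation(down)
  expect_equal(s$pearson_r, -1.0)
  expect_equal(s$spearman_rho, -1.0)

  flat <- up; flat$rel_host_b <- 50
  s <- crosshost_correlation(flat)
  expect_true(is.na(s$pearson_r))
  expect_match(s$note, "zero variance")

  expect_error(crosshost_correlation(up[1:2, ]), "at least 3")
})

test_that("fixture correlations match an independently coded oracle", {
  pairs <- pair_hosts(table1_printed_relatives("C_glutamicum"),
                      table1_printed_relatives("B_subtilis"))
  s <- crosshost_correlation(pairs)
  oracle <- oracle_correlations(pairs$rel_host_a, pairs$rel_host_b)
  expect_equal(s$pearson_r, oracle$pearson, tolerance = 1e-12)
  expect_equal(s$spearman_rho, oracle$spearman, tolerance = 1e-12)
  expect_true(abs(s$pearson_r) <= 1 && abs(s$spearman_rho) <= 1)
})

test_that("correlations are invariant under positive affine rescaling", {
  pairs <- pair_hosts(table1_printed_relatives("C_glutamicum"),
                      table1_printed_relatives("B_subtilis"))
  s0 <- crosshost_correlation(pairs)
  resc <- pairs
  resc$rel_host_a <- 0.63 * resc$rel_host_a + 4
  resc$rel_host_b <- 2.1 * resc$rel_host_b + 0.5
  s1 <- crosshost_correlation(resc)
  expect_equal(s1$pearson_r, s0$pearson_r)
  expect_equal(s1$spearman_rho, s0$spearman_rho)
})

test_that("concordance labels match the fixture's flagged SPs", {
  pairs <- pair_hosts(table1_printed_relatives("C_glutamicum"),
                      table1_printed_relatives("B_subtilis"))
  lab <- concordance_classes(pairs)
  cls <- function(sp) as.character(lab$concordance_class[lab$sp_id == sp])
  expect_identical(cls("YwfM"), "discordant_a_high")
  expect_identical(cls("Bpr"), "concordant_high")
  zero <- concordance_classes(data.frame(sp_id = "z", rel_host_a = 0,
                                         rel_host_b = 0))
  expect_identical(as.character(zero$concordance_class), "concordant_low")
  counts <- attr(lab, "class_counts")
  expect_equal(sum(counts), nrow(lab))
})

test_that("swapping hosts mirrors discordant labels and fixes concordant ones", {
  pairs <- pair_hosts(table1_printed_relatives("C_glutamicum"),
                      table1_printed_relatives("B_subtilis"))
  fwd <- concordance_classes(pairs)
  swapped <- data.frame(sp_id = pairs$sp_id, rel_host_a = pairs$rel_host_b,
                        rel_host_b = pairs$rel_host_a)
  bwd <- concordance_classes(swapped)
  map <- c(concordant_high = "concordant_high", concordant_low = "concordant_low",
           discordant_a_high = "discordant_b_high",
           discordant_b_high = "discordant_a_high")
  expect_identical(unname(map[as.character(fwd$concordance_class)]),
                   as.character(bwd$concordance_class))
})

test_that("estimated rank correlation recovers the generating correlation", {
  set.seed(91)
  n <- 2000
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  # bivariate normal: population Spearman = (6/pi) asin(rho/2)
  rho_s <- (6 / pi) * asin(rho / 2)
  pairs <- data.frame(sp_id = as.character(seq_len(n)),
                      rel_host_a = x, rel_host_b = y)
  s <- crosshost_correlation(pairs)
  se <- 1 / sqrt(n - 3)
  expect_lt(abs(s$spearman_rho - rho_s), 3 * se)
  expect_lt(abs(s$pearson_r - rho), 3 * se)
})
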