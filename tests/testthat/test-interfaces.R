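test_that("the packaged two-host table loads with its documented caveats", {
  tab <- load_table1()
  cg <- tab[tab$host == "C_glutamicum", ]
  bs <- tab[tab$host == "B_subtilis", ]
  expect_equal(nrow(cg), 64)
  expect_equal(nrow(bs), 64)
  expect_match(attr(tab, "caveats"), "64 rows")
  # series maxima sit on the Epr rows
  expect_equal(max(cg$mean_activity_U_per_mL), 13.1)
  expect_identical(cg$sp_id[which.max(cg$mean_activity_U_per_mL)], "Epr")
  expect_equal(max(bs$mean_activity_U_per_mL), 4.7)
  expect_identical(bs$sp_id[which.max(bs$mean_activity_U_per_mL)], "Epr")
  expect_true(all(tab$relative_activity_pct >= 0 &
                    tab$relative_activity_pct <= 100))
  # duplicate entries preserved for repeatedly recovered SPs
  expect_gt(sum(duplicated(cg$sp_id)), 0)
})

test_that("activity tables are validated row by row", {
  ok <- data.frame(clone_id = c("c1", "c2"), sp_id = c("Epr", ""),
                   host = "H", replicate = 1, activity = c(1.5, 0.2),
                   units = c("U/mL", "kU/L"))
  f <- tempfile(fileext = ".csv")
  write.csv(ok, f, row.names = FALSE)
  df <- read_activity_table(f)
  expect_equal(df$activity, c(1.5, 0.2))
  expect_true(all(df$units == "U/mL"))

  # unit round trip is lossless (the two labels share one numeric scale)
  f2 <- tempfile(fileext = ".csv")
  df$units <- "kU/L"
  write.csv(df, f2, row.names = FALSE)
  expect_equal(read_activity_table(f2)$activity, df$activity)

  empty <- tempfile(fileext = ".csv")
  writeLines("clone_id,sp_id,host,replicate,activity,units", empty)
  expect_error(read_activity_table(empty), "no data rows")

  bad_unit <- ok; bad_unit$units <- c("U/mL", "mU/mL")
  f3 <- tempfile(fileext = ".csv")
  write.csv(bad_unit, f3, row.names = FALSE)
  expect_error(read_activity_table(f3), "unknown unit 'mU/mL'.*row 2")

  bad_num <- ok; bad_num$activity <- c("1.5", "fast")
  f4 <- tempfile(fileext = ".csv")
  write.csv(bad_num, f4, row.names = FALSE)
  expect_error(read_activity_table(f4), "`activity`, row 2")

  f5 <- tempfile(fileext = ".csv")
  write.csv(ok[, -3], f5, row.names = FALSE)
  expect_error(read_activity_table(f5), "missing column.*host")
})

test_that("atomic CSV writes land complete and readable", {
  d <- file.path(tempfile(), "nested")
  p <- write_csv_atomic(data.frame(a = 1:3, b_U_per_mL = c(0.1, 0.2, 0.3)),
                        file.path(d, "out.csv"))
  expect_true(file.exists(p))
  back <- read.csv(p)
  expect_equal(back$b_U_per_mL, c(0.1, 0.2, 0.3))
  expect_length(list.files(d, pattern = "\\.tmp$"), 0)
})

test_that("the paper-preset pipeline is deterministic and complete", {
  cfg <- list(preset = "paper", seed = 3, out_dir = tempfile(),
              replicates = 100)
  out <- run_pipeline(cfg)
  expect_true(all(file.exists(unlist(out$files))))
  # the occupancy report carries the analytic per-member probabilities
  occ <- read.csv(out$files$occupancy)
  expect_equal(occ$probability_per_member[occ$m %in% 1:4],
               multiplicity_pmf(66, 148, 1:4))
  # both correlation coefficients are reported for the fixture comparison
  summ <- read.csv(out$files$comparison)
  expect_true(all(c("pearson_r", "spearman_rho") %in% summ$quantity))
  expect_true(all(is.finite(summ$value)))

  cfg2 <- cfg; cfg2$out_dir <- tempfile()
  out2 <- run_pipeline(cfg2)
  for (key in setdiff(names(out$files), "log")) {
    expect_identical(readLines(out$files[[key]]),
                     readLines(out2$files[[key]]),
                     info = paste("stage:", key))
  }
})

test_that("the synthetic-preset pipeline writes campaign, truth and phenotypes", {
  out <- run_pipeline(list(preset = "synthetic", seed = 5,
                           out_dir = tempfile(), replicates = 50,
                           n_clones = 20, n_replicates = 4,
                           replicate_cv = 0))
  camp <- read.csv(out$files$campaign)
  expect_true(all(c("clone_id", "sp_id", "host", "replicate", "activity",
                    "units") %in% names(camp)))
  truth <- read.csv(out$files$truth)
  pheno <- read.csv(out$files$phenotypes)
  # zero replicate noise: every clone mean equals its SP's true activity
  m <- merge(pheno, truth, by = "sp_id")
  expect_equal(m$mean_activity_U_per_mL, m$true_activity_U_per_mL,
               tolerance = 1e-12)
})

test_that("yaml configs drive the pipeline", {
  cfg_file <- tempfile(fileext = ".yaml")
  out_dir <- tempfile()
  writeLines(c("preset: paper", paste0("out_dir: ", out_dir), "seed: 4",
               "replicates: 50"), cfg_file)
  out <- run_pipeline(cfg_file)
  expect_true(file.exists(file.path(out_dir, "design_report.csv")))
  log <- readLines(out$files$log)
  expect_true(any(grepl("seed: 4", log)))
  expect_true(any(grepl("replicates: 50", log)))
})
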