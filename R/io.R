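#' Load the packaged two-host cutinase activity table
#'
#' Transcription of a published comparison of extracellular cutinase
#' activities per Sec signal peptide in two hosts (*C. glutamicum* screened
#' fresh, *B. subtilis* values carried over from the earlier screen of the
#' same library). Repeated `sp_id` rows are SPs recovered in several
#' independent clones and are preserved as printed.
#'
#' Transcription caveats (carried in the `"caveats"` attribute): the table
#' lists 64 entries although 66 sequenced clones are reported, so its
#' multiplicity census (24/9/6/1 members at m = 1..4) matches the reported
#' relative occurrences only at m = 2; printed relative activities were
#' computed from unrounded means, so recomputing them from the rounded
#' activity column can deviate by a few tenths of a percentage point; and the
#' *B. subtilis* series has no per-row SDs (a blanket 25% relative error is
#' stated for it), stored here as `NA`.
#'
#' @return Data frame with columns `table_row`, `sp_id`, `host`
#'   (`C_glutamicum` / `B_subtilis`), `mean_activity_U_per_mL`,
#'   `sd_activity_U_per_mL`, `relative_activity_pct`, `relative_sd_pct`;
#'   attribute `caveats` (character).
#' @examples
#' tab <- load_table1()
#' subset(tab, host == "C_glutamicum" & sp_id == "Epr")
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_cutinase_activities.csv",
                      package = "secscreen", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(tab, "caveats") <- paste(
    "Transcribed table: 64 rows vs. 66 reported sequenced clones;",
    "multiplicity census matches reported relative occurrences only at m = 2;",
    "printed relative activities derive from unrounded means;",
    "B. subtilis SDs not printed per row (blanket 25% relative error)."
  )
  tab
}

#' Read a clone activity table
#'
#' Long-format schema: one row per replicate measurement with columns
#' `clone_id`, `sp_id` (may be empty when the insert is unknown), `host`,
#' `replicate`, `activity`, `units`. Units are restricted to `U/mL` and
#' `kU/L`; the two are numerically identical (1 umol min^-1 mL^-1 = 1 kU/L)
#' and the returned table is expressed in `U/mL`. Errors name the offending
#' row and column.
#'
#' @param path path to a CSV file.
#' @return Data frame in the schema above with `activity` in U/mL.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(clone_id = "c1", sp_id = "Epr", host = "H",
#'                      replicate = 1, activity = 2.5, units = "kU/L"),
#'           f, row.names = FALSE)
#' read_activity_table(f)
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("clone_id", "sp_id", "host", "replicate", "activity", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("activity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("activity table has no data rows", call. = FALSE)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(df[[col]] %in% c("", "NA")))
    bad <- c(bad, which(df[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop("non-numeric value in column `", col, "`, row ", min(bad),
           call. = FALSE)
    }
    x
  }
  df$replicate <- num("replicate")
  df$activity <- num("activity")
  bad_units <- which(!df$units %in% c("U/mL", "kU/L"))
  if (length(bad_units)) {
    stop("unknown unit '", df$units[bad_units[1]], "' in column `units`, row ",
         bad_units[1], " (allowed: U/mL, kU/L)", call. = FALSE)
  }
  ## kU/L and U/mL coincide numerically; normalise the label only
  df$units <- "U/mL"
  if (any(df$activity < 0)) {
    stop("negative activity in column `activity`, row ",
         which(df$activity < 0)[1], call. = FALSE)
  }
  df
}

#' Atomically write a data frame as CSV
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so readers never observe a partially written file. Dialect:
#' comma-separated, UTF-8, `.` decimal, header row, no row names.
#'
#' @param x data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_csv_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(x, tmp, row.names = FALSE, fileEncoding = "UTF-8")
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("could not move temporary file into place at ", path, call. = FALSE)
  }
  invisible(path)
}

#' Run the screening-analysis pipeline end to end
#'
#' Orders the stages as a campaign runs them: occupancy design, picking
#' simulation, phenotype aggregation/normalization/ranking, and (for the
#' two-host preset) the cross-host comparison. Two presets:
#'
#' * `"paper"`: the published study conditions (N = 148 members, n = 66
#'   picks) with the packaged two-host activity table as phenotype input.
#' * `"synthetic"`: a fully simulated campaign from [gen_true_activities()]
#'   and [gen_campaign()], whose ground truth is written alongside the
#'   results for validation.
#'
#' All outputs are plain CSV with unit-suffixed column names, written
#' atomically; a run log records package/R versions, the seed, and every
#' parameter in force. Given the same config and seed the result files are
#' byte-identical (the log's timestamp line aside).
#'
#' @param config a named list, or path to a YAML file with the same fields:
#'   `preset` (`"paper"`/`"synthetic"`), `seed`, `out_dir`, and optional
#'   overrides `library_size`, `picks`, `replicates` (simulation campaigns),
#'   `n_clones`, `n_replicates`, `replicate_cv`, `target_coverage`.
#' @return Invisibly, a named list of written file paths plus the in-memory
#'   stage results.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(preset = "paper", seed = 1,
#'                          out_dir = tempfile(), replicates = 200))
#' names(out$files)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path", call. = FALSE)
  preset <- match.arg(config$preset %||% "paper", c("paper", "synthetic"))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  N <- as.integer(config$library_size %||% 148L)
  n <- as.integer(config$picks %||% 66L)
  replicates <- as.integer(config$replicates %||% 1000L)
  target <- config$target_coverage %||% 0.95

  files <- list(); results <- list()
  lib <- library_design(N)
  plan <- pick_plan(n, N, target_coverage = target)

  ## stage 1: occupancy design report
  occ <- expected_multiplicity_spectrum(n, N, m_max = min(n, 8L))
  occ$probability <- multiplicity_pmf(n, N, occ$m)
  design <- data.frame(
    quantity = c("library_size", "picks", "oversampling_factor",
                 "coverage_probability", "coverage_3x", "coverage_4x",
                 sprintf("required_picks_for_%.2f", target)),
    value = c(N, n, n / N, coverage_probability(n, N),
              coverage_probability(3L * N, N), coverage_probability(4L * N, N),
              required_picks(target, N)))
  files$design <- write_csv_atomic(design, file.path(out_dir, "design_report.csv"))
  names(occ) <- c("m", "expected_members_count", "probability_per_member")
  files$occupancy <- write_csv_atomic(occ, file.path(out_dir, "occupancy_spectrum.csv"))
  results$design <- design; results$occupancy <- occ

  ## stage 2: picking simulation
  sim <- replicate_campaigns(plan, lib, replicates = replicates, seed = seed)
  files$simulation <- write_csv_atomic(sim$summary,
                                       file.path(out_dir, "simulation_summary.csv"))
  results$simulation <- sim$summary

  if (preset == "paper") {
    tab <- load_table1()
    pheno <- data.frame(sp_id = tab$sp_id, host = tab$host,
                        mean_activity = tab$mean_activity_U_per_mL,
                        sd_activity = tab$sd_activity_U_per_mL)
    pheno <- normalize_by_max(pheno)
    pheno <- do.call(rbind, lapply(split(pheno, pheno$host), rank_sps))
    rownames(pheno) <- NULL
    names(pheno) <- c("sp_id", "host", "mean_activity_U_per_mL",
                      "sd_activity_U_per_mL", "relative_activity_pct",
                      "relative_sd_pct")
    files$phenotypes <- write_csv_atomic(pheno, file.path(out_dir, "phenotypes.csv"))
    results$phenotypes <- pheno

    a <- pheno[pheno$host == "C_glutamicum", ]
    b <- pheno[pheno$host == "B_subtilis", ]
    pairs <- pair_hosts(a, b)
    pairs <- concordance_classes(pairs)
    corr <- crosshost_correlation(pairs)
    files$pairs <- write_csv_atomic(
      data.frame(pairs, check.names = FALSE),
      file.path(out_dir, "crosshost_pairs.csv"))
    summ <- data.frame(quantity = c("pearson_r", "spearman_rho", "n_pairs"),
                       value = c(corr$pearson_r, corr$spearman_rho, corr$n_pairs))
    files$comparison <- write_csv_atomic(summ, file.path(out_dir, "crosshost_summary.csv"))
    results$pairs <- pairs; results$comparison <- corr
  } else {
    n_clones <- as.integer(config$n_clones %||% n)
    n_reps <- as.integer(config$n_replicates %||% 8L)
    cv <- config$replicate_cv %||% 0.15
    acts <- gen_true_activities(N, mode = "fixture", seed = seed)
    truth <- campaign_truth(lib, acts, replicate_cv = cv, seed = seed)
    campaign <- gen_campaign(truth, n_clones = n_clones, n_replicates = n_reps)
    files$campaign <- write_csv_atomic(campaign, file.path(out_dir, "campaign.csv"))
    truth_df <- data.frame(sp_id = truth$sp_id,
                           true_activity_U_per_mL = as.numeric(truth$true_activity_per_sp))
    files$truth <- write_csv_atomic(truth_df, file.path(out_dir, "truth.csv"))
    agg <- aggregate_activity_table(campaign)
    agg <- rank_sps(normalize_by_max(agg))
    names(agg) <- c("clone_id", "sp_id", "host", "mean_activity_U_per_mL",
                    "sd_activity_U_per_mL", "n_replicates",
                    "relative_activity_pct", "relative_sd_pct")
    files$phenotypes <- write_csv_atomic(agg, file.path(out_dir, "phenotypes.csv"))
    results$campaign <- campaign; results$phenotypes <- agg; results$truth <- truth
  }

  ## run log: every parameter in force, versions, seed
  log_lines <- c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("secscreen_version: ",
           as.character(utils::packageVersion("secscreen"))),
    paste0("r_version: ", R.version.string),
    paste0("preset: ", preset),
    paste0("seed: ", seed),
    paste0("library_size: ", N),
    paste0("picks: ", n),
    paste0("replicates: ", replicates),
    paste0("outputs: ", paste(basename(unlist(files)), collapse = ", ")))
  log_path <- file.path(out_dir, "run_log.txt")
  tmp <- tempfile(tmpdir = out_dir, fileext = ".tmp")
  writeLines(log_lines, tmp)
  file.rename(tmp, log_path)
  files$log <- log_path

  invisible(list(files = files, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
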