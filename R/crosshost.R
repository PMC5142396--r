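#' Pair per-SP relative activities between two hosts
#'
#' Inner join of two max-normalized host series on `sp_id`. Signal peptides
#' recovered in several clones appear as repeated rows; these are collapsed
#' by the mean of their relative activities before joining (set
#' `collapse = FALSE` to join per-clone rows by position within each SP
#' instead). SPs present in only one series are reported in the
#' `unmatched_a` / `unmatched_b` attributes.
#'
#' @param records_a,records_b data frames with `sp_id` and
#'   `relative_activity_pct` columns (e.g. from [normalize_by_max()]).
#' @param collapse collapse repeated SP entries by mean before joining
#'   (default `TRUE`).
#' @return Data frame with columns `sp_id`, `rel_host_a`, `rel_host_b`;
#'   attributes `unmatched_a`, `unmatched_b`.
#' @examples
#' a <- data.frame(sp_id = c("Epr", "Pel"), relative_activity_pct = c(100, 14.5))
#' b <- data.frame(sp_id = c("Epr", "Pel"), relative_activity_pct = c(100, 57.2))
#' pair_hosts(a, b)
#' @export
pair_hosts <- function(records_a, records_b, collapse = TRUE) {
  for (r in list(records_a, records_b)) {
    if (!all(c("sp_id", "relative_activity_pct") %in% names(r))) {
      stop("records need `sp_id` and `relative_activity_pct` columns",
           call. = FALSE)
    }
  }
  squash <- function(r) {
    if (collapse) {
      agg <- stats::aggregate(relative_activity_pct ~ sp_id, data = r, FUN = mean)
      agg
    } else {
      r$.occ <- stats::ave(seq_len(nrow(r)), r$sp_id, FUN = seq_along)
      r[, c("sp_id", ".occ", "relative_activity_pct")]
    }
  }
  a <- squash(records_a); b <- squash(records_b)
  by <- if (collapse) "sp_id" else c("sp_id", ".occ")
  pairs <- merge(a, b, by = by, suffixes = c("_a", "_b"))
  if (nrow(pairs) == 0) stop("no SPs shared between the two series", call. = FALSE)
  out <- data.frame(sp_id = pairs$sp_id,
                    rel_host_a = pairs$relative_activity_pct_a,
                    rel_host_b = pairs$relative_activity_pct_b,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rel_host_a, out$sp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched_a") <- setdiff(unique(records_a$sp_id), out$sp_id)
  attr(out, "unmatched_b") <- setdiff(unique(records_b$sp_id), out$sp_id)
  out
}

#' Correlation between two hosts' relative activities
#'
#' Pearson correlation on the paired relative activities and Spearman rank
#' correlation (mid-ranks for ties). When either series has zero variance the
#' coefficients are undefined and returned as `NA` with a note. No hypothesis
#' test is attached: whether cross-host performance "transfers" is judged on
#' the coefficients and the scatter itself.
#'
#' @param pairs data frame from [pair_hosts()] (columns `rel_host_a`,
#'   `rel_host_b`), at least 3 rows.
#' @return An object of class `comparison_summary`: list with `pearson_r`,
#'   `spearman_rho`, `n_pairs` and `note`.
#' @examples
#' p <- data.frame(sp_id = letters[1:3], rel_host_a = c(1, 2, 3) * 10,
#'                 rel_host_b = c(1, 2, 3) * 10)
#' crosshost_correlation(p)
#' @export
crosshost_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  x <- pairs$rel_host_a; y <- pairs$rel_host_b
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                          n_pairs = nrow(pairs),
                          note = "zero variance in one series; correlation undefined"),
                     class = "comparison_summary"))
  }
  structure(list(pearson_r = stats::cor(x, y, method = "pearson"),
                 spearman_rho = stats::cor(x, y, method = "spearman"),
                 n_pairs = nrow(pairs),
                 note = NULL),
            class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("Cross-host comparison over", x$n_pairs, "SPs:", x$note, "\n")
  } else {
    cat(sprintf("Cross-host comparison over %d SPs: Pearson r = %.3f, Spearman rho = %.3f\n",
                x$n_pairs, x$pearson_r, x$spearman_rho))
  }
  invisible(x)
}

#' Label SP pairs as concordant or discordant between hosts
#'
#' A pair is discordant when the two relative activities differ by more than
#' `ratio_threshold`-fold, with both values floored at `floor_pct` so that
#' near-zero denominators do not blow up the ratio
#' (`discordant_a_high`/`discordant_b_high` by which host is larger).
#' Otherwise the pair is `concordant_high` when both relatives reach
#' `high_threshold_pct`, else `concordant_low`. Swapping the two hosts swaps
#' the discordant labels and leaves concordant labels fixed.
#'
#' @param pairs data frame from [pair_hosts()].
#' @param high_threshold_pct both-axes threshold separating concordant high
#'   from low performers (default 50).
#' @param ratio_threshold fold-difference beyond which a pair is discordant
#'   (default 4).
#' @param floor_pct floor applied to both relatives before taking the ratio
#'   (default 2 percentage points).
#' @return `pairs` with a `concordance_class` factor column added, plus a
#'   `class_counts` attribute (named integer vector over the four classes).
#' @examples
#' p <- data.frame(sp_id = c("YwfM", "Bpr"), rel_host_a = c(85.5, 84.8),
#'                 rel_host_b = c(7.7, 63.6))
#' concordance_classes(p)$concordance_class
#' @export
concordance_classes <- function(pairs, high_threshold_pct = 50,
                                ratio_threshold = 4, floor_pct = 2) {
  if (high_threshold_pct <= 0 || ratio_threshold <= 0 || floor_pct <= 0) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  a <- pmax(pairs$rel_host_a, floor_pct)
  b <- pmax(pairs$rel_host_b, floor_pct)
  lvls <- c("concordant_high", "concordant_low",
            "discordant_a_high", "discordant_b_high")
  cls <- ifelse(a / b > ratio_threshold, "discordant_a_high",
         ifelse(b / a > ratio_threshold, "discordant_b_high",
         ifelse(pairs$rel_host_a >= high_threshold_pct &
                pairs$rel_host_b >= high_threshold_pct,
                "concordant_high", "concordant_low")))
  pairs$concordance_class <- factor(cls, levels = lvls)
  attr(pairs, "class_counts") <- table(pairs$concordance_class)
  pairs
}
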