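#' Mean and sample standard deviation of replicate activities
#'
#' @param values numeric vector of replicate activities (U/mL), length >= 1.
#' @return List with `mean`, `sd` (n-1 denominator; 0 for a single value) and
#'   `n`.
#' @examples
#' aggregate_replicates(c(4, 6))
#' @export
aggregate_replicates <- function(values) {
  if (length(values) < 1) stop("need at least one replicate", call. = FALSE)
  if (any(!is.finite(values))) stop("replicates must be finite", call. = FALSE)
  list(mean = mean(values),
       sd = if (length(values) == 1L) 0 else stats::sd(values),
       n = length(values))
}

#' Aggregate a clone activity table into per-record statistics
#'
#' Collapses the long replicate table (one row per replicate measurement)
#' into one row per clone, keeping the SP identity and host. Input follows
#' the activity-table schema of [read_activity_table()].
#'
#' @param activities data frame with columns `clone_id`, `sp_id`, `host`,
#'   `replicate`, `activity` (U/mL).
#' @return Data frame with columns `clone_id`, `sp_id`, `host`,
#'   `mean_activity`, `sd_activity`, `n_replicates`.
#' @examples
#' df <- data.frame(clone_id = "c1", sp_id = "Epr", host = "H", replicate = 1:2,
#'                  activity = c(4, 6))
#' aggregate_activity_table(df)
#' @export
aggregate_activity_table <- function(activities) {
  need <- c("clone_id", "sp_id", "host", "replicate", "activity")
  miss <- setdiff(need, names(activities))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- interaction(activities$clone_id, activities$host, drop = TRUE)
  rows <- lapply(split(activities, key), function(d) {
    agg <- aggregate_replicates(d$activity)
    data.frame(clone_id = d$clone_id[1], sp_id = d$sp_id[1], host = d$host[1],
               mean_activity = agg$mean, sd_activity = agg$sd,
               n_replicates = agg$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$host, -out$mean_activity, out$sp_id), , drop = FALSE]
}

#' Max-normalize activities within each host series
#'
#' Expresses every record's mean activity as a percentage of the maximum mean
#' in its own host series (the record attaining the maximum gets exactly
#' 100). A host series whose activities are all zero has no defined maximum
#' scale and raises an error.
#'
#' @param records data frame with at least `mean_activity` and (if several
#'   hosts are present) `host`. A `sd_activity` column, when present, is
#'   scaled by the same factor into `relative_sd_pct`.
#' @return `records` with columns `relative_activity_pct` (and
#'   `relative_sd_pct` if SDs were present) added or overwritten.
#' @examples
#' df <- data.frame(sp_id = c("A", "B"), host = "H", mean_activity = c(13.1, 10.5))
#' normalize_by_max(df)$relative_activity_pct
#' @export
normalize_by_max <- function(records) {
  if (!"mean_activity" %in% names(records)) {
    stop("`records` must have a `mean_activity` column", call. = FALSE)
  }
  host <- if ("host" %in% names(records)) records$host else rep("all", nrow(records))
  for (h in unique(host)) {
    idx <- which(host == h)
    mx <- max(records$mean_activity[idx])
    if (mx <= 0) {
      stop("host series '", h, "' is all zero; maximum undefined",
           call. = FALSE)
    }
    records$relative_activity_pct[idx] <- 100 * records$mean_activity[idx] / mx
    if ("sd_activity" %in% names(records)) {
      records$relative_sd_pct[idx] <- 100 * records$sd_activity[idx] / mx
    }
  }
  records
}

#' Order records by decreasing mean activity
#'
#' Ties are broken lexicographically by `sp_id` so the ordering is total and
#' reproducible.
#'
#' @param records data frame with `mean_activity` and `sp_id` columns.
#' @return `records` reordered.
#' @examples
#' rank_sps(data.frame(sp_id = c("B", "A"), mean_activity = c(1, 2)))
#' @export
rank_sps <- function(records) {
  if (nrow(records) == 0) return(records)
  records[order(-records$mean_activity, records$sp_id), , drop = FALSE]
}

#' Reference panel of strains with known signal-peptide inserts
#'
#' A panel anchors classification of unknown clones: each entry is the
#' activity distribution (mean, SD) measured for a strain whose SP insert is
#' known, typically including an empty-vector control.
#'
#' @param sp_id character vector of panel identities.
#' @param mean_activity,sd_activity numeric vectors (U/mL), SDs `>= 0`.
#' @return An object of class `reference_panel` (a data frame).
#' @examples
#' reference_panel(c("NprE", "empty"), c(5, 0.05), c(0.3, 0.05))
#' @export
reference_panel <- function(sp_id, mean_activity, sd_activity) {
  if (length(sp_id) < 1) stop("panel needs at least one entry", call. = FALSE)
  if (length(mean_activity) != length(sp_id) ||
      length(sd_activity) != length(sp_id)) {
    stop("panel columns must have equal length", call. = FALSE)
  }
  if (any(sd_activity < 0)) stop("panel SDs must be >= 0", call. = FALSE)
  if (anyDuplicated(sp_id)) stop("panel sp_ids must be unique", call. = FALSE)
  structure(data.frame(sp_id = as.character(sp_id),
                       mean_activity = mean_activity,
                       sd_activity = sd_activity,
                       stringsAsFactors = FALSE),
            class = c("reference_panel", "data.frame"))
}

#' Classify an unknown clone against a reference panel
#'
#' A panel entry is a candidate when the clone's activity falls inside the
#' entry's acceptance interval `mean +/- k_sigma * s`, where `s` combines the
#' panel SD with the clone's own SD in quadrature. A single candidate is an
#' unambiguous call; several candidates form an ambiguity set (phenotypes
#' indistinguishable at `k_sigma`, resolvable only by sequencing); if no
#' interval contains the activity the nearest entry by standardized distance
#' is returned, flagged `nearest_only`.
#'
#' @param activity clone activity in U/mL (a single number or an
#'   `activity_measurement` from [activity_from_slope()]).
#' @param panel a [reference_panel()].
#' @param k_sigma half-width of the acceptance interval in combined SDs
#'   (default 2).
#' @param clone_sd optional SD of the clone's own replicate activities
#'   (default 0).
#' @param clone_id identifier carried into the result.
#' @return An object of class `classification_result`: list with `clone_id`,
#'   `assigned` (character vector of candidate sp_ids), `scores` (named
#'   standardized distances to every panel entry) and `nearest_only` flag.
#' @examples
#' pan <- reference_panel(c("NprE", "YpjP"), c(5, 2), c(0.3, 0.2))
#' classify_clone(5.1, pan)
#' @export
classify_clone <- function(activity, panel, k_sigma = 2, clone_sd = 0,
                           clone_id = NA_character_) {
  stopifnot(inherits(panel, "reference_panel"))
  if (inherits(activity, "activity_measurement")) {
    activity <- activity$activity_U_per_mL
  }
  if (k_sigma <= 0) stop("`k_sigma` must be > 0", call. = FALSE)
  if (clone_sd < 0) stop("`clone_sd` must be >= 0", call. = FALSE)
  s <- sqrt(panel$sd_activity^2 + clone_sd^2)
  dist_abs <- abs(activity - panel$mean_activity)
  scores <- dist_abs / pmax(s, .Machine$double.eps)
  names(scores) <- panel$sp_id
  inside <- dist_abs <= k_sigma * s
  nearest_only <- !any(inside)
  assigned <- if (nearest_only) {
    panel$sp_id[which.min(scores)]
  } else {
    panel$sp_id[inside]
  }
  structure(list(clone_id = clone_id, assigned = assigned, scores = scores,
                 nearest_only = nearest_only, k_sigma = k_sigma),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Clone", if (is.na(x$clone_id)) "" else x$clone_id, "->",
      paste(x$assigned, collapse = " | "),
      if (x$nearest_only) "(nearest only)"
      else if (length(x$assigned) > 1) "(ambiguous)" else "", "\n")
  invisible(x)
}

#' Groups of panel entries with indistinguishable phenotypes
#'
#' Two panel entries overlap when their `mean +/- k_sigma * sd` intervals
#' intersect; groups are the transitive closure (connected components) of
#' this overlap relation. A group of size > 1 flags phenotypes that activity
#' alone cannot separate, so plasmid sequencing is required to resolve clone
#' identity within it.
#'
#' @inheritParams classify_clone
#' @return List of character vectors, each a group of mutually reachable
#'   sp_ids, ordered by decreasing group mean activity.
#' @examples
#' pan <- reference_panel(c("NprE", "AmyE", "YwmC"), c(5, 1.0, 1.1),
#'                        c(0.2, 0.15, 0.15))
#' distinguishability_groups(pan)
#' @export
distinguishability_groups <- function(panel, k_sigma = 2) {
  stopifnot(inherits(panel, "reference_panel"))
  if (k_sigma <= 0) stop("`k_sigma` must be > 0", call. = FALSE)
  n <- nrow(panel)
  lo <- panel$mean_activity - k_sigma * panel$sd_activity
  hi <- panel$mean_activity + k_sigma * panel$sd_activity
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && lo[i] <= hi[j] && lo[j] <= hi[i]) {
      parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(panel$sp_id, roots)
  means <- vapply(split(panel$mean_activity, roots), mean, numeric(1))
  unname(groups[order(-means)])
}
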