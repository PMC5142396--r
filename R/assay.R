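#' Configuration of the pNPP kinetic activity assay
#'
#' Parameters of the chromogenic p-nitrophenyl-palmitate (pNPP) assay: a
#' sample aliquot is mixed with reaction solution in a microplate well and
#' the release of p-nitrophenol is followed at 410 nm. Activity is computed
#' from the blanked linear slope via the molar extinction coefficient.
#'
#' @param epsilon molar extinction coefficient of p-nitrophenol at 410 nm, in
#'   cm^2/umol (default 15; note 1 cm^2/umol = 1 mM^-1 cm^-1).
#' @param path_length_cm optical path length of the filled well in cm. Plate
#'   readers measure vertically, so the path is set by the liquid column; the
#'   default 0.58 cm corresponds to a 200 uL fill of a standard cylindrical
#'   96-well (diameter ~6.6 mm). Override if the instrument path-corrects.
#' @param sample_volume_uL sample aliquot per well (default 20).
#' @param reaction_volume_uL total reaction volume per well (default 200,
#'   i.e. 20 uL sample + 180 uL reagent).
#' @param min_r2 minimum r-squared of the slope fit below which a measurement
#'   is flagged `poor_fit` (default 0.95).
#' @return An object of class `assay_config`.
#' @examples
#' assay_config()
#' @export
assay_config <- function(epsilon = 15, path_length_cm = 0.58,
                         sample_volume_uL = 20, reaction_volume_uL = 200,
                         min_r2 = 0.95) {
  if (epsilon <= 0 || path_length_cm <= 0) {
    stop("`epsilon` and `path_length_cm` must be > 0", call. = FALSE)
  }
  if (sample_volume_uL <= 0 || reaction_volume_uL <= 0 ||
      sample_volume_uL > reaction_volume_uL) {
    stop("volumes must be > 0 with sample_volume_uL <= reaction_volume_uL",
         call. = FALSE)
  }
  if (min_r2 < 0 || min_r2 > 1) stop("`min_r2` must be in [0, 1]", call. = FALSE)
  structure(list(epsilon = epsilon, path_length_cm = path_length_cm,
                 sample_volume_uL = sample_volume_uL,
                 reaction_volume_uL = reaction_volume_uL,
                 min_r2 = min_r2),
            class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf(paste0("pNPP assay config: epsilon = %g cm^2/umol, ",
                     "path = %g cm, %g uL sample in %g uL, min r2 = %g\n"),
              x$epsilon, x$path_length_cm, x$sample_volume_uL,
              x$reaction_volume_uL, x$min_r2))
  invisible(x)
}

#' One well's kinetic absorbance trace
#'
#' @param well_id character well identifier.
#' @param times numeric vector of read times in seconds, strictly increasing,
#'   length >= 3 (nominally every 25 s).
#' @param absorbances A410 readings, same length as `times`.
#' @param role `"sample"` or `"blank"`.
#' @param dilution_factor pre-dilution of the supernatant applied before
#'   loading the well (`>= 1`; 1 = undiluted).
#' @return An object of class `kinetic_trace`.
#' @examples
#' kinetic_trace("A1", seq(0, 250, 25), 0.05 + 0.002 * seq(0, 250, 25))
#' @export
kinetic_trace <- function(well_id, times, absorbances, role = "sample",
                          dilution_factor = 1) {
  role <- match.arg(role, c("sample", "blank"))
  if (length(times) != length(absorbances) || length(times) < 3) {
    stop("`times` and `absorbances` must be equal length >= 3", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1", call. = FALSE)
  structure(list(well_id = as.character(well_id), times = as.numeric(times),
                 absorbances = as.numeric(absorbances), role = role,
                 dilution_factor = dilution_factor),
            class = "kinetic_trace")
}

#' Least-squares slope of an absorbance trace
#'
#' Ordinary least-squares fit of A410 against time, reported per minute. For
#' a constant trace (zero variance in absorbance) the slope is 0 and the
#' r-squared is defined as 0. An optional lag trim drops leading points
#' (mixing lag) by choosing the contiguous window of at least `min_window`
#' points ending at the last read that maximises r-squared.
#'
#' @param trace a [kinetic_trace()].
#' @param trim_lag logical; search over starting points for the best-fitting
#'   tail window (default `FALSE`: use all points).
#' @param min_window minimum number of points retained when trimming.
#' @return List with `slope_per_min`, `r2`, and `n_points` used.
#' @examples
#' tr <- kinetic_trace("A1", seq(0, 250, 25), 0.05 + 0.002 * seq(0, 250, 25))
#' fit_slope(tr)  # slope 0.12 / min, r2 = 1
#' @export
fit_slope <- function(trace, trim_lag = FALSE, min_window = 5L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$times; a <- trace$absorbances
  if (stats::var(t) == 0) stop("zero time variance", call. = FALSE)
  starts <- 1L
  if (trim_lag && length(t) > min_window) {
    starts <- seq_len(length(t) - min_window + 1L)
  }
  best <- NULL
  for (s in starts) {
    f <- ols_slope(t[s:length(t)], a[s:length(a)])
    if (is.null(best) || f$r2 > best$r2) {
      best <- f
      best$n_points <- length(t) - s + 1L
    }
  }
  list(slope_per_min = best$slope * 60, r2 = best$r2, n_points = best$n_points)
}

## closed-form OLS on (t in s, A); slope in per-second
ols_slope <- function(t, a) {
  sxx <- sum((t - mean(t))^2)
  sxy <- sum((t - mean(t)) * (a - mean(a)))
  syy <- sum((a - mean(a))^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else (sxy^2) / (sxx * syy)
  list(slope = slope, r2 = r2)
}

#' Blank a sample slope
#'
#' Subtracts the water-blank slope (spontaneous pNPP hydrolysis and drift)
#' from the sample slope.
#'
#' @param sample_slope,blank_slope slopes in 1/min.
#' @return Blanked slope in 1/min (may be negative; downstream conversion
#'   flags non-positive slopes).
#' @examples
#' blank_correct(0.12, 0.02)
#' @export
blank_correct <- function(sample_slope, blank_slope) {
  if (any(!is.finite(sample_slope)) || any(!is.finite(blank_slope))) {
    stop("slopes must be finite", call. = FALSE)
  }
  sample_slope - blank_slope
}

#' Volumetric enzyme activity from a blanked slope
#'
#' Beer-Lambert inversion of the kinetic read-out. The p-nitrophenol
#' formation rate in the well is `slope / (epsilon * d)` in umol mL^-1
#' min^-1; scaling by the reaction-to-sample volume ratio and the supernatant
#' pre-dilution gives the activity of the undiluted supernatant in U/mL
#' (1 U = 1 umol/min; U/mL is numerically equal to kU/L). Non-positive
#' blanked slopes are reported as activity 0 with a `below_detection` flag
#' rather than as negative activities.
#'
#' @param slope_per_min blanked slope, 1/min.
#' @param cfg an [assay_config()].
#' @param dilution_factor supernatant pre-dilution (`>= 1`).
#' @param fit_r2 optional r-squared of the slope fit, carried through and
#'   checked against `cfg$min_r2`.
#' @return An object of class `activity_measurement`: list with
#'   `activity_U_per_mL`, `slope_per_min`, `fit_r2`, `flags` (character
#'   vector, possibly empty), and `path_length_cm` used.
#' @examples
#' activity_from_slope(0.087, assay_config(), dilution_factor = 1)  # 0.1 U/mL
#' @export
activity_from_slope <- function(slope_per_min, cfg = assay_config(),
                                dilution_factor = 1, fit_r2 = NA_real_) {
  stopifnot(inherits(cfg, "assay_config"))
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1", call. = FALSE)
  denom <- cfg$epsilon * cfg$path_length_cm
  if (denom <= 0) stop("epsilon * path length must be > 0", call. = FALSE)
  flags <- character(0)
  if (slope_per_min <= 0) {
    activity <- 0
    flags <- c(flags, "below_detection")
  } else {
    rate_well <- slope_per_min / denom  # umol / mL / min in the well
    activity <- rate_well *
      (cfg$reaction_volume_uL / cfg$sample_volume_uL) * dilution_factor
  }
  if (!is.na(fit_r2) && fit_r2 < cfg$min_r2) flags <- c(flags, "poor_fit")
  structure(list(activity_U_per_mL = activity,
                 slope_per_min = slope_per_min,
                 fit_r2 = fit_r2,
                 flags = flags,
                 path_length_cm = cfg$path_length_cm),
            class = "activity_measurement")
}

#' @export
print.activity_measurement <- function(x, ...) {
  cat(sprintf("Activity: %.4g U/mL (slope %.4g /min, r2 %s)%s\n",
              x$activity_U_per_mL, x$slope_per_min,
              ifelse(is.na(x$fit_r2), "NA", sprintf("%.3f", x$fit_r2)),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Reduce a long-format plate of kinetic traces to activities
#'
#' Takes the long CSV schema (`well_id`, `role`, `time_s`, `A410`,
#' `dilution_factor`), fits a slope per well, averages the blank-well slopes,
#' blanks every sample slope, and converts to volumetric activity. If the
#' plate contains no blank wells the blank slope is taken as 0 and every
#' result is flagged `no_blank`.
#'
#' @param traces data frame with columns `well_id`, `role`
#'   (`sample`/`blank`), `time_s`, `A410`, `dilution_factor`.
#' @param cfg an [assay_config()].
#' @param trim_lag passed to [fit_slope()].
#' @return Data frame with one row per sample well: `well_id`,
#'   `slope_per_min` (blanked), `r2`, `activity_U_per_mL`, `flags`
#'   (comma-separated, empty string when none).
#' @examples
#' tr <- gen_traces(activity = 2, dilution = 2, noise_sd = 0, seed = 1)
#' df <- rbind(as.data.frame(tr$sample), as.data.frame(tr$blank))
#' quantify_traces(df)
#' @export
quantify_traces <- function(traces, cfg = assay_config(), trim_lag = FALSE) {
  need <- c("well_id", "role", "time_s", "A410", "dilution_factor")
  missing_cols <- setdiff(need, names(traces))
  if (length(missing_cols)) {
    stop("traces are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(traces$role), c("sample", "blank"))
  if (length(bad_role)) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  wells <- split(traces, traces$well_id)
  fits <- lapply(wells, function(w) {
    w <- w[order(w$time_s), ]
    tr <- kinetic_trace(w$well_id[1], w$time_s, w$A410, role = w$role[1],
                        dilution_factor = w$dilution_factor[1])
    c(fit_slope(tr, trim_lag = trim_lag),
      list(role = tr$role, dilution = tr$dilution_factor,
           well_id = tr$well_id))
  })
  blank_slopes <- vapply(Filter(function(f) f$role == "blank", fits),
                         function(f) f$slope_per_min, numeric(1))
  no_blank <- length(blank_slopes) == 0
  blank_mean <- if (no_blank) 0 else mean(blank_slopes)
  samples <- Filter(function(f) f$role == "sample", fits)
  rows <- lapply(samples, function(f) {
    blanked <- blank_correct(f$slope_per_min, blank_mean)
    am <- activity_from_slope(blanked, cfg, f$dilution, fit_r2 = f$r2)
    flags <- am$flags
    if (no_blank) flags <- c(flags, "no_blank")
    data.frame(well_id = f$well_id,
               slope_per_min = blanked,
               r2 = f$r2,
               activity_U_per_mL = am$activity_U_per_mL,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(well_id = character(0), slope_per_min = numeric(0),
                      r2 = numeric(0), activity_U_per_mL = numeric(0),
                      flags = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(well_id = x$well_id, role = x$role, time_s = x$times,
             A410 = x$absorbances, dilution_factor = x$dilution_factor,
             stringsAsFactors = FALSE)
}
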