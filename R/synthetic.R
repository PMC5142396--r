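#' Draw per-member true secretion activities
#'
#' Two generators for the latent "true" extracellular activity of each
#' library member: `fixture` resamples (with replacement) the packaged
#' two-host activity table's *C. glutamicum* means, reproducing the empirical
#' spread of a real SP library (~0-13 U/mL, many weak and few strong
#' secreters); `lognormal` draws from a log-normal with the given log-scale
#' parameters.
#'
#' @param N number of members.
#' @param mode `"fixture"` or `"lognormal"`.
#' @param meanlog,sdlog log-normal parameters (used when
#'   `mode = "lognormal"`; defaults 0.5 and 1 give a median ~1.6 U/mL with a
#'   heavy right tail of the fixture's magnitude).
#' @param seed integer seed.
#' @return Numeric vector of `N` non-negative activities (U/mL).
#' @examples
#' gen_true_activities(10, seed = 1)
#' @export
gen_true_activities <- function(N, mode = c("fixture", "lognormal"),
                                meanlog = 0.5, sdlog = 1, seed) {
  mode <- match.arg(mode)
  if (N < 1) stop("`N` must be >= 1", call. = FALSE)
  with_seed(seed, {
    if (mode == "fixture") {
      tab <- load_table1()
      pool <- tab$mean_activity_U_per_mL[tab$host == "C_glutamicum"]
      sample(pool, N, replace = TRUE)
    } else {
      stats::rlnorm(N, meanlog = meanlog, sdlog = sdlog)
    }
  })
}

#' Bundle the ground truth of a synthetic screening campaign
#'
#' @param library a [library_design()].
#' @param true_activities per-member true activities (U/mL), length
#'   `library$N`.
#' @param replicate_cv coefficient of variation of biological replicates
#'   (default 0.15, the mid-range of empirically observed replicate scatter).
#' @param seed integer seed governing all downstream draws.
#' @return An object of class `campaign_truth`.
#' @examples
#' lib <- library_design(5)
#' campaign_truth(lib, c(0, 1, 2, 5, 13), seed = 1)
#' @export
campaign_truth <- function(library, true_activities, replicate_cv = 0.15,
                           seed) {
  stopifnot(inherits(library, "library_design"))
  if (length(true_activities) != library$N) {
    stop("`true_activities` must have length N = ", library$N, call. = FALSE)
  }
  if (any(true_activities < 0)) stop("activities must be >= 0", call. = FALSE)
  if (replicate_cv < 0) stop("`replicate_cv` must be >= 0", call. = FALSE)
  sp_id <- sprintf("SP%03d", seq_len(library$N))
  structure(list(library = library,
                 sp_id = sp_id,
                 true_activity_per_sp = stats::setNames(true_activities, sp_id),
                 replicate_cv = replicate_cv,
                 seed = as.integer(seed)),
            class = "campaign_truth")
}

#' Generate a synthetic clone activity table
#'
#' Draws `n_clones` clones from the library weights with the same categorical
#' sampler the screening simulator uses, then produces `n_replicates`
#' replicate activities per clone as
#' `true_activity * (1 + Normal(0, cv))`, truncated at 0 (the assay floor).
#' The output follows the long activity-table schema consumed by
#' [aggregate_activity_table()] / [read_activity_table()].
#'
#' @param truth a [campaign_truth()].
#' @param n_clones number of clones picked.
#' @param n_replicates replicate measurements per clone.
#' @param host host label written into the table (default `"synthetic"`).
#' @return Data frame with columns `clone_id`, `sp_id`, `host`, `replicate`,
#'   `activity`, `units`; attribute `clone_assignments` (named character
#'   vector clone_id -> sp_id).
#' @examples
#' lib <- library_design(5)
#' tr <- campaign_truth(lib, c(0, 1, 2, 5, 13), replicate_cv = 0.1, seed = 1)
#' head(gen_campaign(tr, n_clones = 4, n_replicates = 2))
#' @export
gen_campaign <- function(truth, n_clones, n_replicates, host = "synthetic") {
  stopifnot(inherits(truth, "campaign_truth"))
  if (n_clones < 1 || n_replicates < 1) {
    stop("`n_clones` and `n_replicates` must be >= 1", call. = FALSE)
  }
  with_seed(truth$seed, {
    members <- draw_picks(n_clones, truth$library)
    clone_id <- sprintf("clone%04d", seq_len(n_clones))
    sp <- truth$sp_id[members]
    true_act <- truth$true_activity_per_sp[members]
    reps <- matrix(
      pmax(0, rep(true_act, each = n_replicates) *
             (1 + stats::rnorm(n_clones * n_replicates, 0, truth$replicate_cv))),
      nrow = n_replicates)
    out <- data.frame(
      clone_id = rep(clone_id, each = n_replicates),
      sp_id = rep(sp, each = n_replicates),
      host = host,
      replicate = rep(seq_len(n_replicates), times = n_clones),
      activity = as.vector(reps),
      units = "U/mL",
      stringsAsFactors = FALSE)
    attr(out, "clone_assignments") <- stats::setNames(sp, clone_id)
    out
  })
}

#' Generate a synthetic pNPP kinetic trace (plus paired blank)
#'
#' Builds the absorbance trace a supernatant of the stated activity would
#' produce under the assay configuration: the well slope is the exact inverse
#' of [activity_from_slope()] for the given dilution, so a zero-noise trace
#' round-trips to the input activity exactly. Gaussian read noise
#' (`noise_sd`, absorbance units) is added per read; the paired blank carries
#' only the background rate.
#'
#' @param activity true supernatant activity in U/mL.
#' @param cfg an [assay_config()].
#' @param dilution pre-dilution applied to the supernatant (`>= 1`).
#' @param duration_s trace duration in seconds (default 300).
#' @param interval_s sampling interval (default 25 s).
#' @param noise_sd SD of additive Gaussian absorbance noise (default 0).
#' @param a0 initial absorbance offset (default 0.05).
#' @param blank_rate background slope in 1/min shared by sample and blank
#'   (default 0.01, slow spontaneous pNPP hydrolysis).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @param well_id,blank_id well identifiers.
#' @return List with elements `sample` and `blank`, both [kinetic_trace()]s.
#' @examples
#' tr <- gen_traces(activity = 2, dilution = 2, noise_sd = 0, seed = 1)
#' fit_slope(tr$sample)$slope_per_min
#' @export
gen_traces <- function(activity, cfg = assay_config(), dilution = 1,
                       duration_s = 300, interval_s = 25, noise_sd = 0,
                       a0 = 0.05, blank_rate = 0.01, seed = 1,
                       well_id = "S1", blank_id = "B1") {
  stopifnot(inherits(cfg, "assay_config"))
  if (activity < 0) stop("`activity` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (duration_s < 3 * interval_s) {
    stop("`duration_s` must span at least 3 sampling intervals", call. = FALSE)
  }
  times <- seq(0, duration_s, by = interval_s)
  ## invert activity = slope/(eps*d) * (Vr/Vs) * dilution
  slope_min <- activity * cfg$epsilon * cfg$path_length_cm /
    (cfg$reaction_volume_uL / cfg$sample_volume_uL) / dilution
  with_seed(seed, {
    noise_s <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
    noise_b <- if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
    list(
      sample = kinetic_trace(well_id, times,
                             a0 + (slope_min + blank_rate) / 60 * times + noise_s,
                             role = "sample", dilution_factor = dilution),
      blank = kinetic_trace(blank_id, times,
                            a0 + blank_rate / 60 * times + noise_b,
                            role = "blank", dilution_factor = 1))
  })
}
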