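#' Multiplicity distribution of a picking campaign
#'
#' Container for the census of a campaign: how many library members were hit
#' exactly `m` times (`m >= 1`), together with the number of picks and the
#' relative occurrence per multiplicity (`counts[m] / n_picks`; the
#' denominator is picks, not members).
#'
#' @param counts named integer vector; names are multiplicities `m >= 1`,
#'   values the number of members hit exactly `m` times.
#' @param n_picks total number of picks in the campaign; must equal
#'   `sum(m * counts[m])`.
#' @return An object of class `multiplicity_distribution` with elements
#'   `counts`, `n_picks` and `relative_occurrence`.
#' @examples
#' multiplicity_distribution(c(`1` = 25, `2` = 9, `3` = 5, `4` = 2), 66)
#' @export
multiplicity_distribution <- function(counts, n_picks) {
  if (is.null(names(counts)) || any(is.na(suppressWarnings(
        as.integer(names(counts)))))) {
    stop("`counts` must be named by integer multiplicities", call. = FALSE)
  }
  m <- as.integer(names(counts))
  counts <- as.integer(counts)
  if (any(m < 1)) stop("multiplicities must be >= 1", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  keep <- counts > 0
  m <- m[keep]; counts <- counts[keep]
  o <- order(m); m <- m[o]; counts <- counts[o]
  if (sum(m * counts) != n_picks) {
    stop("pick conservation violated: sum(m * counts) = ", sum(m * counts),
         " but n_picks = ", n_picks, call. = FALSE)
  }
  counts <- stats::setNames(counts, m)
  structure(list(counts = counts,
                 n_picks = as.integer(n_picks),
                 relative_occurrence = counts / n_picks),
            class = "multiplicity_distribution")
}

#' @export
print.multiplicity_distribution <- function(x, ...) {
  cat("Multiplicity distribution of", x$n_picks, "picks\n")
  print(data.frame(m = as.integer(names(x$counts)),
                   members = as.integer(x$counts),
                   relative_occurrence = round(x$relative_occurrence, 4),
                   row.names = NULL))
  invisible(x)
}

## n categorical draws of member indices; the single shared sampler used by
## both the simulator and the synthetic campaign generator
draw_picks <- function(n, library) {
  if (n == 0L) return(integer(0))
  sample.int(library$N, size = n, replace = TRUE, prob = library$weights)
}

## run `code` under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (length(seed) != 1L || !is.finite(seed) || seed != floor(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate one clone-picking campaign
#'
#' Draws `plan$n` clones independently from the library's weight distribution
#' (sampling with replacement) and returns the resulting multiplicity census.
#' The same seed always reproduces the same campaign.
#'
#' @param plan a [pick_plan()].
#' @param library a [library_design()]; `library$N` must equal `plan$N`.
#' @param seed integer seed for the draw.
#' @return A [multiplicity_distribution()].
#' @examples
#' simulate_picks(pick_plan(66, 148), library_design(148), seed = 1)
#' @export
simulate_picks <- function(plan, library, seed) {
  stopifnot(inherits(plan, "pick_plan"), inherits(library, "library_design"))
  if (plan$N != library$N) {
    stop("plan refers to N = ", plan$N, " but library has N = ", library$N,
         call. = FALSE)
  }
  picks <- with_seed(seed, draw_picks(plan$n, library))
  spectrum_from_picks(picks, plan$n)
}

spectrum_from_picks <- function(picks, n) {
  if (n == 0L) {
    return(multiplicity_distribution(stats::setNames(integer(0), integer(0)), 0L))
  }
  per_member <- tabulate(picks)
  tab <- table(per_member[per_member > 0])
  multiplicity_distribution(stats::setNames(as.integer(tab), names(tab)), n)
}

#' Replicate many simulated campaigns and summarise multiplicity ranges
#'
#' Repeats [simulate_picks()] `replicates` times from a single random stream
#' seeded once, so extending `replicates` reproduces all earlier campaigns
#' unchanged. Per multiplicity `m` it reports the minimum, mean and maximum
#' member count across replicates, the kind of "number ranges" used to judge
#' whether an observed campaign census is compatible with equiprobable
#' picking.
#'
#' @inheritParams simulate_picks
#' @param replicates integer `>= 1`, number of simulated campaigns.
#' @return An object of class `simulation_result`: list with
#'   `replicate_spectra` (list of [multiplicity_distribution()]), `summary`
#'   (data frame: `m`, `count_min`, `count_mean`, `count_max`,
#'   `relative_occurrence_mean`) and `seed`.
#' @examples
#' sim <- replicate_campaigns(pick_plan(66, 148), library_design(148),
#'                            replicates = 100, seed = 1)
#' sim$summary
#' @export
replicate_campaigns <- function(plan, library, replicates, seed) {
  stopifnot(inherits(plan, "pick_plan"), inherits(library, "library_design"))
  if (length(replicates) != 1L || replicates < 1 ||
      replicates != floor(replicates)) {
    stop("`replicates` must be a single integer >= 1", call. = FALSE)
  }
  spectra <- with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      spectrum_from_picks(draw_picks(plan$n, library), plan$n)
    })
  })
  m_max <- max(c(1L, unlist(lapply(spectra, function(s)
    as.integer(names(s$counts))))))
  mat <- vapply(spectra, function(s) {
    v <- numeric(m_max)
    idx <- as.integer(names(s$counts))
    v[idx] <- s$counts
    v
  }, numeric(m_max))
  mat <- matrix(mat, nrow = m_max)  # guard m_max == 1 drop
  summ <- data.frame(
    m = seq_len(m_max),
    count_min = apply(mat, 1, min),
    count_mean = rowMeans(mat),
    count_max = apply(mat, 1, max),
    relative_occurrence_mean = rowMeans(mat) / plan$n
  )
  structure(list(replicate_spectra = spectra, summary = summ,
                 seed = as.integer(seed)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation of", length(x$replicate_spectra), "campaigns (seed",
      paste0(x$seed, ")\n"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Relative occurrence of each multiplicity in an observed campaign
#'
#' The campaign-level convention: the number of members recovered exactly `m`
#' times divided by the number of picks. This is the empirical counterpart
#' that screening reports quote next to the per-member binomial
#' probabilities; the two have different denominators and are not expected to
#' be equal.
#'
#' @param observed a [multiplicity_distribution()] with `n_picks >= 1`.
#' @return Named numeric vector, one entry per multiplicity present.
#' @examples
#' md <- multiplicity_distribution(c(`1` = 25, `2` = 9, `3` = 5, `4` = 2), 66)
#' empirical_relative_occurrence(md)
#' @export
empirical_relative_occurrence <- function(observed) {
  stopifnot(inherits(observed, "multiplicity_distribution"))
  if (observed$n_picks < 1) {
    stop("relative occurrence undefined for a campaign with zero picks",
         call. = FALSE)
  }
  observed$counts / observed$n_picks
}

#' Monte-Carlo frequency with which one member is hit exactly m times
#'
#' Simulates many campaigns and returns the fraction in which a designated
#' library member is recovered exactly `m` times, together with the
#' Monte-Carlo standard error. This is the simulation-side estimate of
#' [multiplicity_pmf()], computed by actually drawing picks. Draws are taken
#' in chunks from one seeded stream for speed; the estimate is deterministic
#' given the seed.
#'
#' @inheritParams simulate_picks
#' @param member index of the designated member (default 1).
#' @param m multiplicity of interest (default 1).
#' @param replicates number of simulated campaigns.
#' @return List with `frequency`, `se` (binomial standard error) and
#'   `replicates`.
#' @examples
#' member_hit_frequency(pick_plan(66, 148), library_design(148),
#'                      replicates = 1000, seed = 1)
#' @export
member_hit_frequency <- function(plan, library, member = 1L, m = 1L,
                                 replicates, seed) {
  stopifnot(inherits(plan, "pick_plan"), inherits(library, "library_design"))
  if (member < 1 || member > library$N) {
    stop("`member` must index a library member", call. = FALSE)
  }
  hits_m <- with_seed(seed, {
    total <- 0L
    chunk <- 20000L
    done <- 0L
    while (done < replicates) {
      r <- min(chunk, replicates - done)
      draws <- matrix(draw_picks(plan$n * r, library), nrow = plan$n)
      total <- total + sum(colSums(draws == member) == m)
      done <- done + r
    }
    total
  })
  p <- hits_m / replicates
  list(frequency = p,
       se = sqrt(p * (1 - p) / replicates),
       replicates = as.integer(replicates))
}

#' Symmetric-Dirichlet library weights
#'
#' One-knob model of an unevenly represented pool (e.g. unequal plasmid
#' abundance after pooled cloning): member weights drawn from a symmetric
#' Dirichlet with the given concentration. Small concentrations give strongly
#' skewed pools; large concentrations approach uniformity.
#'
#' @param N library size.
#' @param concentration positive Dirichlet concentration parameter.
#' @param seed integer seed.
#' @return A [library_design()] with random weights.
#' @examples
#' dirichlet_library(148, concentration = 1, seed = 1)
#' @export
dirichlet_library <- function(N, concentration = 1, seed) {
  if (concentration <= 0) stop("`concentration` must be > 0", call. = FALSE)
  w <- with_seed(seed, {
    g <- stats::rgamma(N, shape = concentration, rate = 1)
    g / sum(g)
  })
  library_design(N, w)
}
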