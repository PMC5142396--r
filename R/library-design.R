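#' Describe a plasmid library to be sampled by clone picking
#'
#' A screening campaign picks colonies at random after transforming a pooled
#' plasmid library. Picking is modelled as sampling with replacement from the
#' `N` distinct members, member `i` being drawn with probability `weights[i]`.
#' The default is equiprobable sampling, the idealisation that every member of
#' the pool had the same chance to end up in a picked clone.
#'
#' @param N positive integer, number of distinct library members.
#' @param weights numeric vector of length `N` of selection probabilities;
#'   non-negative and summing to 1 (within `1e-9`). Default: uniform, `1/N`
#'   each.
#' @return An object of class `library_design` with elements `N` and
#'   `weights`.
#' @examples
#' lib <- library_design(148)
#' lib$weights[1]  # 1/148
#' @export
library_design <- function(N, weights = NULL) {
  if (length(N) != 1L || is.na(N) || N < 1 || N != as.integer(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.null(weights)) {
    weights <- rep(1 / N, N)
  }
  if (length(weights) != N) {
    stop("`weights` must have length N = ", N, call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("`weights` must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1 (within 1e-9); got ", sum(weights),
         call. = FALSE)
  }
  structure(list(N = N, weights = as.numeric(weights)),
            class = "library_design")
}

#' Describe a picking plan for a screening campaign
#'
#' @param n non-negative integer, number of clones to pick.
#' @param N positive integer, library size the plan refers to.
#' @param target_coverage optional probability in `[0, 1)`: the desired
#'   chance that a designated library member appears at least once (used by
#'   design queries, see [required_picks()]).
#' @return An object of class `pick_plan` with elements `n`, `N`,
#'   `oversampling_factor` (`n/N`) and `target_coverage`.
#' @examples
#' pick_plan(66, 148)$oversampling_factor
#' @export
pick_plan <- function(n, N, target_coverage = NULL) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != as.integer(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  if (length(N) != 1L || is.na(N) || N < 1 || N != as.integer(N)) {
    stop("`N` must be a single positive integer", call. = FALSE)
  }
  if (!is.null(target_coverage)) {
    if (!is.numeric(target_coverage) || target_coverage < 0 ||
        target_coverage >= 1) {
      stop("`target_coverage` must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), N = as.integer(N),
                 oversampling_factor = n / N,
                 target_coverage = target_coverage),
            class = "pick_plan")
}

#' @export
print.library_design <- function(x, ...) {
  uni <- all(abs(x$weights - 1 / x$N) < 1e-12)
  cat("Library design: N =", x$N,
      if (uni) "members, uniform weights\n" else "members, non-uniform weights\n")
  invisible(x)
}

#' @export
print.pick_plan <- function(x, ...) {
  cat(sprintf("Pick plan: n = %d picks from N = %d (oversampling %.2f-fold)\n",
              x$n, x$N, x$oversampling_factor))
  if (!is.null(x$target_coverage)) {
    cat(sprintf("  target coverage: %.3f\n", x$target_coverage))
  }
  invisible(x)
}
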