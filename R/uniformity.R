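#' Tie-breaking perturbation of query offsets
#'
#' Offsets stored at fixed decimal precision produce exact ties at large
#' sample sizes, which distorts the null distribution of the
#' Kolmogorov-Smirnov statistic. This adds an independent uniform draw on
#' `[-5e-6, +5e-6]` seconds to each offset, below the stored precision of the
#' logs, breaking ties (almost surely) without materially moving any offset.
#'
#' @param offsets Numeric vector of offsets in seconds.
#' @param seed Optional seed for reproducibility.
#' @return The perturbed offsets; no value moves by more than `5e-6` s.
#' @export
perturb_offsets <- function(offsets, seed = NULL) {
  with_seed(seed, offsets + stats::runif(length(offsets), -5e-6, 5e-6))
}

#' Kolmogorov-Smirnov test of offset uniformity
#'
#' Tests a song's query offsets against the uniform distribution on
#' `[0, length_s]` with a two-sided KS test. Under the uniform null a query
#' would be equally likely at any moment of the song; rejection licenses the
#' event-locked analyses downstream. When `seed` is supplied the offsets are
#' first passed through [perturb_offsets()]; perturbed values are clamped
#' back to `(0, length_s]` (a bias of at most `5e-6` s) so the support
#' assumption holds. The p-value uses the asymptotic approximation, adequate
#' for the intended sample sizes (thousands to millions).
#'
#' @param offsets Numeric vector of offsets in seconds (non-empty).
#' @param length_s Track length in seconds.
#' @param seed Optional perturbation seed; `NULL` tests the offsets as given.
#' @return An object of class `uniformity_test`: a list with
#'   `ks_statistic`, `p_value`, `n` and `seed`.
#' @examples
#' r <- ks_uniformity_test(runif(500, 0, 200), 200, seed = 1)
#' r$p_value > 0.001 # uniform data: typically no rejection
#' @export
ks_uniformity_test <- function(offsets, length_s, seed = NULL) {
  if (length(offsets) == 0L) stop("offsets must be non-empty")
  stopifnot(is_scalar_num(length_s), length_s > 0)
  if (!is.null(seed)) offsets <- perturb_offsets(offsets, seed)
  offsets <- pmin(pmax(offsets, .Machine$double.xmin), length_s)
  kt <- suppressWarnings(
    stats::ks.test(offsets, "punif", min = 0, max = length_s)
  )
  structure(
    list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
         n = length(offsets), seed = seed),
    class = "uniformity_test"
  )
}

#' @export
print.uniformity_test <- function(x, ...) {
  cat(sprintf("<uniformity_test> n = %d, D = %.4g, p = %.3g\n",
              x$n, x$ks_statistic, x$p_value))
  invisible(x)
}
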