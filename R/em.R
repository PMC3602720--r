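# EM-inspired handling of left-censored illness onsets.
#
# Individuals already ill at baseline (patterns E/F) have an onset age W
# known only to lie in (A0, Ab). The algorithm alternates between fitting
# the coefficients with W fixed and replacing each W by its conditional
# expectation given baseline illness:
#   1. fit on patterns A-D only;
#   2. for each E/F individual, compute the posterior probability P_k that
#      onset fell in subinterval k of the [A0, Ab] grid, the expected
#      subinterval k* = floor(sum k P_k), and the expected within-
#      subinterval transition time (truncated-exponential mean);
#   3. refit on all patterns with the imputed sojourn Ab - W;
#   4. iterate to joint convergence of theta and the log-likelihood.

#' Posterior distribution of the onset subinterval for a left-censored onset
#'
#' For an individual found ill at baseline, splits `[A0, Ab]` into
#' subintervals of length `h` and computes, via Bayes' theorem, the
#' probability `P_k` that the illness onset occurred in subinterval `k`,
#' conditional on being healthy at `A0` and ill (and alive) at `Ab`. The
#' numerator for subinterval `k` is the product of healthy-survival factors
#' before `k`, the within-subinterval transition probability
#' `(q12/lambda1) (1 - exp(-lambda1 h))` at `k`, and illness-survival
#' factors after `k` with the sojourn clock started at the left limit of
#' `k`.
#'
#' @param theta A [smid_coef].
#' @param record An E/F record from a [smid_panel].
#' @param A0 Age at which the individual is assumed healthy; `A0 < Ab`.
#' @param h Grid resolution (years).
#' @return A list of class `smid_onset_posterior`: `grid`, `P`
#'   (probabilities summing to 1), `lam1` (healthy escape rates at the left
#'   limits).
#' @export
onset_posterior <- function(theta, record, A0, h = 0.25) {
  if (!record$pattern %in% c("E", "F"))
    stop("onset_posterior applies to left-censored (E/F) records")
  if (A0 >= record$Ab) stop("A0 must be below the baseline age")
  g <- build_grid(A0, record$Ab, h)
  x <- record$x
  a <- g$left
  q12 <- intensity_1j(theta, a, 2, x)
  q13 <- intensity_1j(theta, a, 3, x)
  lam1 <- q12 + q13
  # q23 at subinterval m > k, onset at the left limit of k: outer structure
  # exp(e23 + (s23+g) a_m - g a_k)
  s23 <- unname(theta$beta23[2L])
  e23 <- fold_intercept(theta$beta23, x)
  qa <- exp(cap_lp(e23 + (s23 + theta$gamma) * a))    # length K
  suffix <- rev(cumsum(rev(qa * g$width)))            # sum_{m>=k} qa_m w_m
  suffix <- c(suffix[-1L], 0)                         # sum_{m>k}
  # cap: survival beyond e^-1e6 is indistinguishable from 0 but must stay
  # finite so the Bayes normalisation is well defined for wild interim theta
  ill <- pmin(exp(cap_lp(-theta$gamma * a)) * suffix, 1e6)
  P <- onset_posterior_probs(lam1, q12, g$width, ill_cumhaz = ill)
  structure(list(grid = g, P = P, lam1 = lam1), class = "smid_onset_posterior")
}

# Core Bayes computation from raw rate ingredients (unit-testable with
# hand-crafted rates). ill_cumhaz[k] = cumulative 2->3 hazard over
# subintervals after k given onset at the left limit of k.
onset_posterior_probs <- function(lam1, q12, width, ill_cumhaz) {
  K <- length(lam1)
  healthy_cum <- c(0, cumsum(lam1 * width))[seq_len(K)]  # sum_{m<k}
  lw <- lam1 * width
  # log of (q12/lam1)(1 - exp(-lam1 w)); -> log(q12 w) as lam1 -> 0
  log_p12 <- ifelse(lw < 1e-10, log(q12 * width), log(q12 / lam1) + log(-expm1(-lw)))
  lognum <- -healthy_cum + log_p12 - ill_cumhaz
  if (all(!is.finite(lognum)))
    stop("degenerate onset posterior: all subinterval probabilities are zero")
  P <- exp(lognum - max(lognum, na.rm = TRUE))
  P[!is.finite(P)] <- 0
  P / sum(P)
}

#' Expected onset subinterval
#'
#' The mean of the multinomial subinterval distribution, floored to an
#' integer index and clamped to `[1, K]`.
#'
#' @param posterior A [onset_posterior] result (or a bare probability
#'   vector).
#' @return An integer subinterval index.
#' @export
expected_subinterval <- function(posterior) {
  P <- if (inherits(posterior, "smid_onset_posterior")) posterior$P else posterior
  k <- floor(sum(seq_along(P) * P))
  max(1L, min(as.integer(k), length(P)))
}

#' Expected transition time within a subinterval
#'
#' Mean of an exponential waiting time with rate `lambda`, truncated to
#' `[0, h]`: `1/lambda - h / expm1(lambda * h)`. Tends to `h/2` as
#' `lambda -> 0` and to `1/lambda` for `h` much larger than `1/lambda`.
#'
#' @param lambda Non-negative escape rate (per year).
#' @param h Subinterval width (years).
#' @return A time in `(0, h)`.
#' @export
expected_time_within <- function(lambda, h) {
  ifelse(lambda * h < 1e-8, h / 2, 1 / lambda - h / expm1(lambda * h))
}

#' Impute a left-censored onset age
#'
#' Combines the expected subinterval and the expected within-subinterval
#' time into an onset age `W = A0 + (k_star - 1) h + t`, clamped just below
#' the baseline age.
#'
#' @param A0 Assumed healthy age.
#' @param k_star Expected subinterval index.
#' @param t Expected time within the subinterval.
#' @param h Grid resolution.
#' @param Ab Baseline age (for the upper clamp); optional.
#' @return The imputed onset age.
#' @export
impute_onset_age <- function(A0, k_star, t, h, Ab = Inf) {
  W <- A0 + (k_star - 1) * h + t
  if (W >= Ab) {
    warning("imputed onset age at or beyond baseline; clamped")
    W <- Ab - 1e-6
  }
  W
}

# one E-step: expected onset age for a single E/F record
impute_record_onset <- function(theta, record, A0, h) {
  post <- onset_posterior(theta, record, A0, h)
  ks <- expected_subinterval(post)
  t <- expected_time_within(post$lam1[ks], post$grid$width[ks])
  impute_onset_age(A0, ks, t, h, Ab = record$Ab)
}
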