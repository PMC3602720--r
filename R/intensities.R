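# Transition intensities and the Gompertz reparameterisation.
#
# All ages in years, all rates per year. Linear predictors are capped at
# +/- 50 before exponentiation so that a wild step of the optimiser cannot
# produce Inf/NaN intensities during line search.

LP_CAP <- 50

cap_lp <- function(lp) pmin(pmax(lp, -LP_CAP), LP_CAP)

# effective intercept after folding constant extra covariates into beta[1]
fold_intercept <- function(beta, x) {
  if (length(beta) > 2L) {
    if (length(x) != length(beta) - 2L)
      stop("covariate values do not match the coefficient layout")
    unname(beta[1L] + sum(beta[-(1:2)] * x))
  } else unname(beta[1L])
}

#' Transition intensities out of the healthy state
#'
#' Evaluates the log-linear intensity `q_1j(A) = exp(Z(A) %*% beta_1j)` for a
#' transition from the healthy state to either illness (`j = 2`) or death
#' (`j = 3`), at age `A`.
#'
#' @param theta A [smid_coef] object.
#' @param A Age(s) in years (vectorised).
#' @param j Target state, 2 (illness) or 3 (death).
#' @param x Named or ordered values of the extra covariates (constant over
#'   age); omit for the `(1, A)` layout.
#' @return Intensity (rate per year), same length as `A`.
#' @examples
#' th <- smid_coef(c(-8.78, 0.065), c(-10.31, 0.093), c(-5.92, 0.052), -0.11)
#' intensity_1j(th, A = 65, j = 3)   # exp(-10.31 + 0.093 * 65)
#' @export
intensity_1j <- function(theta, A, j, x = numeric(0)) {
  stopifnot(inherits(theta, "smid_coef"), j %in% c(2, 3))
  beta <- if (j == 2) theta$beta12 else theta$beta13
  exp(cap_lp(fold_intercept(beta, x) + unname(beta[2L]) * A))
}

#' Illness-to-death transition intensity
#'
#' Evaluates `q_23(A | W) = exp(Z(A) %*% beta_23 + gamma * (A - W))`, the
#' death intensity for an individual who entered the illness state at age
#' `W`. The term `gamma * (A - W)` makes the process semi-Markov: the rate
#' depends on the time already spent ill, not only on current age.
#'
#' @inheritParams intensity_1j
#' @param W Age at illness onset (years); must satisfy `W <= A`.
#' @return Intensity (rate per year).
#' @export
intensity_23 <- function(theta, A, W, x = numeric(0)) {
  stopifnot(inherits(theta, "smid_coef"))
  if (any(A < W)) stop("intensity_23 requires A >= W")
  beta <- theta$beta23
  exp(cap_lp(fold_intercept(beta, x) + unname(beta[2L]) * A + theta$gamma * (A - W)))
}

#' Gompertz form of the illness-to-death hazard
#'
#' For a fixed onset age `W` (and constant extra covariates) the hazard
#' `q_23(A | W)` as a function of the sojourn time `T2 = A - W` is a Gompertz
#' hazard `alpha23 * exp(xi23 * T2)` with
#' `alpha23 = exp(beta_0.23 + beta_A.23 * W + x-terms)` and
#' `xi23 = gamma + beta_A.23`. When `xi23 < 0` the sojourn distribution is
#' improper: a fraction of ill individuals never dies (see
#' [eventual_transition_fraction]).
#'
#' @inheritParams intensity_23
#' @return A list with components `alpha23` (rate at onset, per year) and
#'   `xi23` (shape, per year).
#' @examples
#' th <- smid_coef(c(-8.78, 0.065), c(-10.31, 0.093), c(-5.92, 0.052), -0.11)
#' gompertz_sojourn(th, W = 65)  # alpha23 = exp(-2.54), xi23 = -0.058
#' @export
gompertz_sojourn <- function(theta, W, x = numeric(0)) {
  stopifnot(inherits(theta, "smid_coef"))
  beta <- theta$beta23
  list(alpha23 = exp(fold_intercept(beta, x) + unname(beta[2L]) * W),
       xi23 = unname(theta$gamma + beta[2L]))
}

#' Fraction of ill individuals who eventually die under a Gompertz hazard
#'
#' Under the hazard `alpha * exp(xi * t)` on the sojourn time scale, the
#' survivor function tends to `exp(alpha / xi)` as `t` grows when `xi < 0`
#' (improper Gompertz), so only `1 - exp(alpha / xi)` of individuals ever
#' experience the event. When `xi >= 0` the distribution is proper and the
#' fraction is 1.
#'
#' @param alpha Positive rate at sojourn time 0 (per year).
#' @param xi Shape parameter (per year).
#' @return A probability in `(0, 1]`.
#' @examples
#' g <- gompertz_sojourn(
#'   smid_coef(c(-8.78, 0.065), c(-10.31, 0.093), c(-5.92, 0.052), -0.11),
#'   W = 65)
#' eventual_transition_fraction(g$alpha23, g$xi23)  # ~ 0.743
#' @export
eventual_transition_fraction <- function(alpha, xi) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  ifelse(xi >= 0, 1, 1 - exp(alpha / xi))
}
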