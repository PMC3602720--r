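#' Regression coefficients of the illness-death model
#'
#' Bundles the three coefficient vectors of the transition-intensity
#' regressions and the sojourn-time coefficient into a single object.
#' Each transition `1->2`, `1->3` and `2->3` has a log-linear intensity
#' `exp(Z(A) %*% beta)` where `Z(A) = (1, A, X_1, ..., X_r)` is the design
#' vector at age `A` (years); the `2->3` intensity carries the extra term
#' `gamma * (A - W)` for the time already spent in the illness state, `W`
#' being the age at illness onset.
#'
#' @param beta12,beta13,beta23 Numeric vectors of equal length
#'   `2 + length(covariates)`: intercept, age slope (per year), then one
#'   slope per extra covariate.
#' @param gamma Scalar: per-year effect of the sojourn time `A - W` on the
#'   log intensity of the `2->3` transition.
#' @param covariates Character vector of extra covariate names (may be
#'   empty, giving the restricted `(1, A)` layout).
#'
#' @return An object of class `smid_coef`.
#' @examples
#' th <- smid_coef(beta12 = c(-8.78, 0.065), beta13 = c(-10.31, 0.093),
#'                 beta23 = c(-5.92, 0.052), gamma = -0.11)
#' th
#' @export
smid_coef <- function(beta12, beta13, beta23, gamma, covariates = character(0)) {
  p <- 2L + length(covariates)
  nm <- c("(Intercept)", "age", covariates)
  for (b in list(beta12, beta13, beta23)) {
    if (length(b) != p)
      stop("each beta vector must have length 2 + number of extra covariates")
    if (!all(is.finite(b))) stop("coefficients must be finite")
  }
  if (length(gamma) != 1L || !is.finite(gamma)) stop("gamma must be a finite scalar")
  structure(list(beta12 = stats::setNames(as.numeric(beta12), nm),
                 beta13 = stats::setNames(as.numeric(beta13), nm),
                 beta23 = stats::setNames(as.numeric(beta23), nm),
                 gamma = as.numeric(gamma),
                 covariates = covariates),
            class = "smid_coef")
}

#' @export
print.smid_coef <- function(x, digits = 4, ...) {
  cat("Illness-death model coefficients\n")
  m <- rbind(`1 -> 2` = x$beta12, `1 -> 3` = x$beta13, `2 -> 3` = x$beta23)
  print(round(m, digits))
  cat("sojourn (gamma):", format(x$gamma, digits = digits), "per year\n")
  invisible(x)
}

# flat parameter vector <-> smid_coef, used by the optimiser
flatten_coef <- function(theta) {
  c(stats::setNames(theta$beta12, paste0("12.", names(theta$beta12))),
    stats::setNames(theta$beta13, paste0("13.", names(theta$beta13))),
    stats::setNames(theta$beta23, paste0("23.", names(theta$beta23))),
    gamma = theta$gamma)
}

unflatten_coef <- function(par, covariates = character(0)) {
  p <- 2L + length(covariates)
  stopifnot(length(par) == 3L * p + 1L)
  smid_coef(beta12 = par[seq_len(p)],
            beta13 = par[p + seq_len(p)],
            beta23 = par[2L * p + seq_len(p)],
            gamma = par[3L * p + 1L],
            covariates = covariates)
}
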