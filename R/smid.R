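#' Fit the semi-Markov illness-death model to a longitudinal panel
#'
#' Maximum-likelihood fit of the three-state illness-death model with
#' piecewise-constant Gompertz-type intensities on the age scale and a
#' sojourn-time effect on the illness-to-death intensity. Interval-censored
#' onsets (patterns A-D) are integrated out of the likelihood; left-censored
#' onsets (patterns E/F, ill at baseline) are imputed by an EM-inspired
#' iteration: fit on A-D, impute each onset age by its conditional
#' expectation given baseline illness, refit on all patterns, and repeat
#' until both the coefficients and the log-likelihood stabilise.
#'
#' @param data A [smid_panel], or a data frame in the panel dialect
#'   (columns `id`, `age`, `state`, `death`, covariates).
#' @param covariates Extra covariate column names (baseline-constant).
#' @param A0 Age at which left-censored individuals are assumed to have
#'   been healthy (years; default 40).
#' @param h Piecewise-constant resolution (years; default 0.25).
#' @param int_res Simpson integration resolution (years; default 0.05).
#' @param settings A full [smid_settings] (overrides `A0`, `h`, `int_res`).
#' @param theta0 Optional starting coefficients.
#' @return An object of class `smid` with components `coefficients`
#'   (a [smid_coef]), `loglik`, `W_imputed` (named onset ages for E/F
#'   individuals), `trace` (per-EM-iteration coefficients and
#'   log-likelihoods), `converged`, `data`, `settings`.
#' @seealso [smid_bootstrap()] for confidence intervals, [smid_gof()] for
#'   microsimulation goodness of fit, [simulate_panel()] to generate data.
#' @examples
#' \donttest{
#' cfg <- scenario_config("I", n_pool = 400, n_keep = 200)
#' pan <- simulate_panel(cfg, seed = 1)
#' fit <- smid(pan, A0 = cfg$A0)
#' summary(fit)
#' }
#' @export
smid <- function(data, covariates = character(0), A0 = 40, h = 0.25,
                 int_res = 0.05, settings = NULL, theta0 = NULL) {
  if (is.null(settings))
    settings <- smid_settings(h = h, int_res = int_res, A0 = A0)
  panel <- if (inherits(data, "smid_panel")) data
           else smid_panel(data, covariates = covariates)
  pat <- patterns_of(panel)
  ef <- which(pat %in% c("E", "F"))
  ad <- which(!seq_along(panel) %in% ef)
  if (length(ad) == 0L) stop("no pattern A-D records: the model is not identifiable")

  # step 1: fit on interval/right-censored patterns only
  fit0 <- fit_mle(subset_panel(panel, ad), theta0 = theta0, settings = settings)
  theta <- fit0$theta
  trace <- list(list(iter = 0L, theta = flatten_coef(theta), loglik = fit0$loglik,
                     max_dtheta = NA_real_))
  W <- rep(NA_real_, length(panel))
  converged <- length(ef) == 0L
  loglik <- fit0$loglik
  loglik_prev2 <- NA_real_
  fit <- fit0
  iter <- 0L

  while (!converged && iter < settings$em_maxit) {
    iter <- iter + 1L
    # E-step: expected onset age for each left-censored individual
    for (i in ef)
      W[i] <- impute_record_onset(theta, panel[[i]], settings$A0, settings$h)
    # M-step: refit on all patterns, warm started
    fit <- fit_mle(panel, theta0 = theta, settings = settings, W = W)
    d_theta <- max(abs(flatten_coef(fit$theta) - flatten_coef(theta)))
    d_ll <- abs(fit$loglik - loglik) / max(1, abs(fit$loglik))
    # the floored expected subinterval makes the E-step discontinuous, so
    # the imputation can settle into a period-2 cycle between adjacent grid
    # cells; a log-likelihood matching the value two iterations back (with
    # theta already stable) is such a cycle, and counts as converged
    d_ll2 <- abs(fit$loglik - loglik_prev2) / max(1, abs(fit$loglik))
    loglik_prev2 <- loglik
    theta <- fit$theta
    loglik <- fit$loglik
    trace[[length(trace) + 1L]] <-
      list(iter = iter, theta = flatten_coef(theta), loglik = loglik,
           max_dtheta = d_theta)
    if (iter > 1L && d_theta < settings$em_tol_theta &&
        (d_ll < settings$em_tol_loglik ||
         (!is.na(d_ll2) && d_ll2 < settings$em_tol_loglik))) converged <- TRUE
  }

  Wimp <- stats::setNames(W[ef], vapply(panel[ef], function(p) as.character(p$id), ""))
  structure(list(coefficients = theta,
                 loglik = loglik,
                 W_imputed = Wimp,
                 trace = trace,
                 em_iterations = iter,
                 converged = converged && fit$converged,
                 inner_converged = fit$converged,
                 grad_norm = fit$grad_norm,
                 n = length(panel),
                 patterns = table(factor(pat, levels = LETTERS[1:6])),
                 data = panel,
                 settings = settings),
            class = "smid")
}

#' @export
print.smid <- function(x, digits = 4, ...) {
  cat("Semi-Markov illness-death model fit\n")
  cat(sprintf("  %d individuals (patterns %s)\n", x$n,
              paste(names(x$patterns), x$patterns, sep = "=", collapse = " ")))
  cat(sprintf("  log-likelihood %.3f, %d EM iteration(s), %s\n", x$loglik,
              x$em_iterations, if (x$converged) "converged" else "NOT converged"))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.smid <- function(object, ...) flatten_coef(object$coefficients)

#' @export
logLik.smid <- function(object, ...) {
  structure(object$loglik, df = length(coef(object)), class = "logLik")
}

#' @export
summary.smid <- function(object, ...) {
  est <- coef(object)
  tab <- data.frame(estimate = est)
  if (!is.null(object$boot)) {
    tab$lower <- object$boot$ci[, "lower"]
    tab$upper <- object$boot$ci[, "upper"]
  }
  structure(list(fit = object, table = tab), class = "summary.smid")
}

#' @export
print.summary.smid <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(round(x$table, digits))
  if (is.null(x$fit$boot))
    cat("(run smid_bootstrap() for confidence intervals)\n")
  invisible(x)
}

#' @export
confint.smid <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot))
    stop("no bootstrap results attached; run smid_bootstrap() first")
  ci <- object$boot$ci[, c("lower", "upper"), drop = FALSE]
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
vcov.smid <- function(object, ...) {
  if (is.null(object$boot))
    stop("no bootstrap results attached; run smid_bootstrap() first")
  stats::cov(object$boot$replicates)
}
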