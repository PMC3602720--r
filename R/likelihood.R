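# Likelihood for the semi-Markov illness-death model under left, right and
# interval censoring.
#
# Two routes compute the same quantities:
#  * likelihood_contribution() is the literal per-individual computation via
#    build_grid()/stay_probability(), kept readable and used in tests;
#  * neg_log_likelihood() is a vectorised evaluation over the whole panel
#    using the closed-form cumulative hazards of cumhaz_loglin(), which are
#    algebraically identical to the explicit subinterval products. The
#    fitter uses the fast route; a test pins the two together.

#' Numerical and optimiser settings for the likelihood
#'
#' @param h Resolution of the piecewise-constant intensity grid (years;
#'   default 0.25, i.e. 3 months).
#' @param int_res Resolution of the composite Simpson rule used to
#'   integrate over the unobserved onset age (years; default 0.05, i.e.
#'   about 18 days). Must not exceed `h`.
#' @param A0 Age (years) at which every left-censored individual is assumed
#'   to have been healthy (default 40).
#' @param reltol,maxit Convergence tolerance and iteration cap for the BFGS
#'   optimiser.
#' @param grad_step Relative step of the central-difference gradient.
#' @param em_tol_theta Absolute convergence tolerance on each coefficient
#'   between EM iterations.
#' @param em_tol_loglik Relative convergence tolerance on the log-likelihood
#'   between EM iterations.
#' @param em_maxit Maximum number of EM iterations.
#' @return A list of class `smid_settings`.
#' @export
smid_settings <- function(h = 0.25, int_res = 0.05, A0 = 40,
                          reltol = 1e-8, maxit = 400, grad_step = 1e-5,
                          em_tol_theta = 1e-2, em_tol_loglik = 1e-6,
                          em_maxit = 50) {
  if (h <= 0 || int_res <= 0) stop("h and int_res must be positive")
  if (int_res > h + 1e-12) stop("int_res must not exceed h")
  structure(list(h = h, int_res = int_res, A0 = A0, reltol = reltol,
                 maxit = maxit, grad_step = grad_step,
                 em_tol_theta = em_tol_theta, em_tol_loglik = em_tol_loglik,
                 em_maxit = em_maxit),
            class = "smid_settings")
}

#' Composite Simpson quadrature
#'
#' Integrates a vectorised function over `[a, b]` with an even number of
#' panels of width at most `resolution` (at least two panels). Exact for
#' cubic polynomials.
#'
#' @param f Vectorised integrand.
#' @param a,b Integration limits, `b >= a`.
#' @param resolution Maximum panel width.
#' @return The integral estimate; 0 when `b == a`.
#' @export
simpson_integrate <- function(f, a, b, resolution) {
  nw <- simpson_nodes(a, b, resolution)
  if (is.null(nw)) return(0)
  sum(nw$w * f(nw$x))
}

simpson_nodes <- function(a, b, resolution) {
  if (b <= a + 1e-12) return(NULL)
  m <- max(2L, 2L * ceiling((b - a) / (2 * resolution)))
  x <- seq(a, b, length.out = m + 1L)
  w <- c(1, rep(c(4, 2), length.out = m - 1L), 1) * (b - a) / (3 * m)
  list(x = x, w = w)
}

# stay probability via the literal grid route; 1 for an empty interval
stay_ll <- function(rate_fun, a0, a1, h) {
  if (a1 <= a0 + 1e-12) return(1)
  g <- build_grid(a0, a1, h)
  stay_probability(rate_fun(g$left), g)
}

#' Likelihood contribution of a single individual
#'
#' Computes the per-individual likelihood contribution of the observation
#' pattern, conditional on the state at baseline. For patterns A-D the
#' unobserved onset age is integrated out over its admissible window by
#' composite Simpson quadrature; exact death ages contribute hazard
#' (density) factors. For patterns E/F the contribution is conditional on
#' the (imputed) onset age `W`, with the sojourn clock running from `W`.
#'
#' @param record One element of a [smid_panel].
#' @param theta A [smid_coef].
#' @param settings A [smid_settings].
#' @param W Onset age for patterns E/F (ignored otherwise).
#' @return A positive likelihood value.
#' @export
likelihood_contribution <- function(record, theta, settings = smid_settings(),
                                    W = NULL) {
  h <- settings$h
  x <- record$x
  Ab <- record$Ab; AN <- record$AN
  lam1 <- function(a) intensity_1j(theta, a, 2, x) + intensity_1j(theta, a, 3, x)
  p11 <- function(a1) stay_ll(lam1, Ab, a1, h)
  p22 <- function(w) stay_ll(function(a) intensity_23(theta, a, w, x), w, AN, h)
  integrand_death <- function(w)
    vapply(w, function(wi) p11(wi) * intensity_1j(theta, wi, 2, x) *
             p22(wi) * intensity_23(theta, AN, wi, x), 0)
  integrand_cens <- function(w)
    vapply(w, function(wi) p11(wi) * intensity_1j(theta, wi, 2, x) * p22(wi), 0)
  switch(record$pattern,
    A = {
      if (record$A20 <= record$A1N) stop("degenerate onset window for pattern A")
      simpson_integrate(integrand_death, record$A1N, record$A20, settings$int_res)
    },
    B = {
      if (record$A20 <= record$A1N) stop("degenerate onset window for pattern B")
      simpson_integrate(integrand_cens, record$A1N, record$A20, settings$int_res)
    },
    C = simpson_integrate(integrand_death, record$A1N, AN, settings$int_res) +
        p11(AN) * intensity_1j(theta, AN, 3, x),
    D = simpson_integrate(integrand_cens, record$A1N, AN, settings$int_res) +
        p11(AN),
    E = {
      if (is.null(W) || W >= Ab) stop("pattern E needs an onset age W < Ab")
      stay_ll(function(a) intensity_23(theta, a, W, x), Ab, AN, h) *
        intensity_23(theta, AN, W, x)
    },
    F = {
      if (is.null(W) || W >= Ab) stop("pattern F needs an onset age W < Ab")
      stay_ll(function(a) intensity_23(theta, a, W, x), Ab, AN, h)
    })
}

# ---- fast vectorised route ------------------------------------------------

# Precompute everything that does not depend on theta: Simpson nodes for the
# onset-age integrals, record indices, covariate matrix.
build_lik_context <- function(panel, settings) {
  n <- length(panel)
  pat <- patterns_of(panel)
  Ab <- vapply(panel, `[[`, 0, "Ab")
  AN <- vapply(panel, `[[`, 0, "AN")
  r <- length(attr(panel, "covariates"))
  X <- if (r) t(vapply(panel, `[[`, numeric(r), "x")) else matrix(0, n, 0)
  lo <- ifelse(pat %in% c("A", "B"), vapply(panel, `[[`, 0, "A1N"),
               ifelse(pat %in% c("C", "D"), vapply(panel, `[[`, 0, "A1N"), NA))
  hi <- ifelse(pat %in% c("A", "B"), vapply(panel, function(p) p$A20 %||% NA_real_, 0),
               ifelse(pat %in% c("C", "D"), AN, NA))
  w <- wt <- numeric(0); ridx <- integer(0)
  for (i in seq_len(n)) {
    if (pat[i] %in% c("E", "F")) next
    nw <- simpson_nodes(lo[i], hi[i], settings$int_res)
    if (is.null(nw)) next
    w <- c(w, nw$x); wt <- c(wt, nw$w); ridx <- c(ridx, rep.int(i, length(nw$x)))
  }
  list(n = n, pat = pat, Ab = Ab, AN = AN, X = X,
       w = w, wt = wt, ridx = ridx,
       death_factor = pat[ridx] %in% c("A", "C"),
       id = vapply(panel, function(p) as.character(p$id), ""),
       h = settings$h)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# Per-record likelihood contributions, vectorised. W is a length-n vector of
# onset ages (used only for E/F records).
lik_vector <- function(ctx, theta, W = rep(NA_real_, ctx$n)) {
  h <- ctx$h
  s12 <- unname(theta$beta12[2L]); s13 <- unname(theta$beta13[2L])
  s23 <- unname(theta$beta23[2L]); g <- theta$gamma
  xb <- function(beta) unname(beta[1L]) + as.vector(ctx$X %*% beta[-(1:2)])
  e12 <- xb(theta$beta12); e13 <- xb(theta$beta13); e23 <- xb(theta$beta23)
  contrib <- numeric(ctx$n)

  i <- ctx$ridx
  if (length(i)) {
    wv <- ctx$w
    L1 <- cumhaz_loglin(e12[i], s12, ctx$Ab[i], wv, h) +
          cumhaz_loglin(e13[i], s13, ctx$Ab[i], wv, h)
    q12w <- exp(cap_lp(e12[i] + s12 * wv))
    L2 <- cumhaz_loglin(e23[i] - g * wv, s23 + g, wv, ctx$AN[i], h)
    term <- exp(-L1) * q12w * exp(-L2)
    q23AN <- exp(cap_lp(e23[i] + s23 * ctx$AN[i] + g * (ctx$AN[i] - wv)))
    term[ctx$death_factor] <- term[ctx$death_factor] * q23AN[ctx$death_factor]
    ints <- rowsum(ctx$wt * term, i)
    contrib[as.integer(rownames(ints))] <- ints[, 1L]
  }

  cd <- which(ctx$pat %in% c("C", "D"))
  if (length(cd)) {
    L1N <- cumhaz_loglin(e12[cd], s12, ctx$Ab[cd], ctx$AN[cd], h) +
           cumhaz_loglin(e13[cd], s13, ctx$Ab[cd], ctx$AN[cd], h)
    direct <- exp(-L1N)
    isC <- ctx$pat[cd] == "C"
    direct[isC] <- direct[isC] * exp(cap_lp(e13[cd][isC] + s13 * ctx$AN[cd][isC]))
    contrib[cd] <- contrib[cd] + direct
  }

  ef <- which(ctx$pat %in% c("E", "F"))
  if (length(ef)) {
    Wef <- W[ef]
    if (anyNA(Wef)) stop("onset ages W are required for patterns E/F")
    L2b <- cumhaz_loglin(e23[ef] - g * Wef, s23 + g, ctx$Ab[ef], ctx$AN[ef], h)
    val <- exp(-L2b)
    isE <- ctx$pat[ef] == "E"
    val[isE] <- val[isE] *
      exp(cap_lp(e23[ef][isE] + s23 * ctx$AN[ef][isE] + g * (ctx$AN[ef][isE] - Wef[isE])))
    contrib[ef] <- val
  }
  contrib
}

#' Negative log-likelihood of a panel
#'
#' Minus the sum of log likelihood contributions over all individuals,
#' conditional on each individual's state at baseline (and, for patterns
#' E/F, on the supplied onset ages).
#'
#' @param panel A [smid_panel].
#' @param theta A [smid_coef].
#' @param settings A [smid_settings].
#' @param W Optional numeric vector of onset ages, one per individual in
#'   panel order (only entries for E/F records are used).
#' @return The negative log-likelihood (0 for an empty panel).
#' @export
neg_log_likelihood <- function(panel, theta, settings = smid_settings(),
                               W = NULL) {
  if (length(panel) == 0L) return(0)
  ctx <- build_lik_context(panel, settings)
  if (is.null(W)) W <- rep(NA_real_, ctx$n)
  L <- lik_vector(ctx, theta, W)
  if (any(!is.finite(L)) || any(L <= 0)) {
    bad <- ctx$id[!is.finite(L) | L <= 0]
    stop("non-positive or non-finite likelihood contribution for id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  -sum(log(L))
}

# objective used by the optimiser: large finite penalty instead of an error
negll_objective <- function(ctx, theta, W) {
  L <- lik_vector(ctx, theta, W)
  if (any(!is.finite(L)) || any(L <= 0)) return(1e10)
  v <- -sum(log(L))
  if (!is.finite(v)) 1e10 else v
}

# crude occurrence/exposure starting values: intercepts at log crude rates,
# slopes and gamma at zero
crude_init <- function(panel) {
  pat <- patterns_of(panel)
  Ab <- vapply(panel, `[[`, 0, "Ab")
  AN <- vapply(panel, `[[`, 0, "AN")
  A1N <- vapply(panel, function(p) p$A1N %||% NA_real_, 0)
  A20 <- vapply(panel, function(p) p$A20 %||% NA_real_, 0)
  healthy <- pat %in% c("A", "B", "C", "D")
  py1 <- sum(A1N[healthy] - Ab[healthy], na.rm = TRUE)
  n12 <- sum(pat %in% c("A", "B"))
  n13 <- sum(pat == "C")
  py2 <- sum(AN[pat %in% c("A", "B")] - A20[pat %in% c("A", "B")], na.rm = TRUE) +
         sum(AN[pat %in% c("E", "F")] - Ab[pat %in% c("E", "F")])
  n23 <- sum(pat %in% c("A", "E"))
  rate <- function(ev, py) (ev + 0.5) / (py + 1)
  r <- length(attr(panel, "covariates"))
  pad <- rep(0, r)
  smid_coef(beta12 = c(log(rate(n12, py1)), 0, pad),
            beta13 = c(log(rate(n13, py1)), 0, pad),
            beta23 = c(log(rate(n23, py2)), 0, pad),
            gamma = 0,
            covariates = attr(panel, "covariates"))
}

# centre the age slope at a_c to decorrelate intercept and slope during
# optimisation; b_centered = b + s * a_c
centre_par <- function(par, p, a_c) {
  for (k in 0:2) par[k * p + 1L] <- par[k * p + 1L] + par[k * p + 2L] * a_c
  par
}
uncentre_par <- function(par, p, a_c) {
  for (k in 0:2) par[k * p + 1L] <- par[k * p + 1L] - par[k * p + 2L] * a_c
  par
}

#' Maximise the panel likelihood for fixed onset ages
#'
#' Quasi-Newton (BFGS) maximisation of the likelihood with
#' central-difference gradients. Onset ages of left-censored individuals
#' are held fixed at `W` (they are updated outside this function by the EM
#' iteration of [smid()]).
#'
#' @inheritParams neg_log_likelihood
#' @param theta0 Starting [smid_coef]; defaults to crude
#'   occurrence/exposure rates.
#' @return A list with elements `theta` (the estimate), `loglik`,
#'   `converged`, `counts` and `grad_norm`.
#' @export
fit_mle <- function(panel, theta0 = NULL, settings = smid_settings(), W = NULL) {
  ctx <- build_lik_context(panel, settings)
  if (is.null(W)) W <- rep(NA_real_, ctx$n)
  if (is.null(theta0)) theta0 <- crude_init(panel)
  covs <- theta0$covariates
  p <- 2L + length(covs)
  a_c <- mean(c(ctx$Ab, ctx$AN))
  fn <- function(parc) {
    th <- unflatten_coef(uncentre_par(parc, p, a_c), covs)
    negll_objective(ctx, th, W)
  }
  gr <- function(parc) {
    st <- settings$grad_step * (abs(parc) + settings$grad_step)
    vapply(seq_along(parc), function(j) {
      up <- dn <- parc
      up[j] <- parc[j] + st[j]; dn[j] <- parc[j] - st[j]
      (fn(up) - fn(dn)) / (2 * st[j])
    }, 0)
  }
  par0 <- centre_par(unname(flatten_coef(theta0)), p, a_c)
  opt <- stats::optim(par0, fn, gr, method = "BFGS",
                      control = list(maxit = settings$maxit,
                                     reltol = settings$reltol))
  g <- gr(opt$par)
  list(theta = unflatten_coef(uncentre_par(opt$par, p, a_c), covs),
       loglik = -opt$value,
       converged = opt$convergence == 0L,
       counts = opt$counts,
       grad_norm = sqrt(sum(g^2)))
}
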