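# Microsimulation goodness of fit: simulate fitted-model replicates cloned
# at the observed baseline and compare Kaplan-Meier survival and state
# prevalence with the observed data.

# simulate one individual forward from baseline under theta
sim_one_from <- function(theta, state, Ab, W, horizon, h) {
  if (state == 1L) {
    tr <- simulate_trajectories(theta, 1L, Ab, horizon, h)
    list(W = tr$W, death = tr$death)
  } else {
    K2 <- ceiling((horizon - Ab) / h + 1e-9)
    if (K2 < 1L) return(list(W = W, death = NA_real_))
    a2 <- Ab + (seq_len(K2) - 1) * h
    q23 <- intensity_23(theta, a2, W)
    d <- invert_pch(stats::rexp(1L), q23, Ab, h)
    list(W = W, death = if (!is.na(d) && d < horizon) d else NA_real_)
  }
}

#' Microsimulate replicates of the observed cohort under the fitted model
#'
#' Each replicate clones the observed baseline exactly (same individuals,
#' baseline ages, baseline states and, for left-censored individuals, the
#' imputed onset age) and simulates each trajectory forward under the
#' fitted coefficients, then applies the visit/censoring design.
#'
#' @param fit A [smid] fit.
#' @param R Number of replicates (default 100).
#' @param seed Integer seed.
#' @param followup,spacing Observation design (years).
#' @return A list of `R` panel data frames, each with a `truth` attribute.
#' @export
microsimulate_fitted <- function(fit, R = 100, seed = NULL,
                                 followup = 12, spacing = 2) {
  stopifnot(inherits(fit, "smid"))
  if (!is.null(seed)) set.seed(seed)
  theta <- fit$coefficients
  h <- fit$settings$h
  panel <- fit$data
  Wmap <- fit$W_imputed
  lapply(seq_len(R), function(r) {
    rows <- lapply(seq_along(panel), function(i) {
      rec <- panel[[i]]
      base_state <- rec$visit_state[1L]
      W0 <- if (base_state == 2L) Wmap[[as.character(rec$id)]] else NA_real_
      tr <- sim_one_from(theta, base_state, rec$Ab, W0, rec$Ab + followup, h)
      d <- observe_trajectory(tr$W, tr$death, rec$Ab, followup, spacing)
      d$id <- rec$id
      attr(d, "sim") <- c(W = tr$W, death = tr$death)
      d
    })
    out <- do.call(rbind, rows)[, c("id", "age", "state", "death")]
    attr(out, "truth") <- data.frame(
      id = vapply(panel, function(p) p$id, panel[[1L]]$id),
      Ab = vapply(panel, `[[`, 0, "Ab"),
      W = vapply(rows, function(d) attr(d, "sim")[["W"]], 0),
      death = vapply(rows, function(d) attr(d, "sim")[["death"]], 0))
    out
  })
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood 95% limits, as a tidy step
#' function.
#'
#' @param time Time to event or censoring (from a common origin).
#' @param status 1 = event, 0 = censored.
#' @return A data frame with columns `time`, `n_risk`, `surv`, `lower`,
#'   `upper` (empty for empty input).
#' @export
km_curve <- function(time, status) {
  if (length(time) == 0L)
    return(data.frame(time = numeric(0), n_risk = numeric(0),
                      surv = numeric(0), lower = numeric(0), upper = numeric(0)))
  sf <- survival::survfit(survival::Surv(time, status) ~ 1, conf.type = "log")
  data.frame(time = sf$time, n_risk = sf$n.risk, surv = sf$surv,
             lower = sf$lower, upper = sf$upper)
}

#' State prevalence over an age grid
#'
#' At each grid age, the fraction of individuals occupying each state among
#' those contributing information at that age: individuals enter at their
#' baseline age, deaths count from their exact death age onwards, and
#' individuals right censored alive drop out after their censoring age.
#' Because illness onsets are interval censored, the observed state-1
#' prevalence is biased upwards relative to the underlying process
#' (individuals are seen in state 2 later than they enter it).
#'
#' @param panel A [smid_panel] or a panel data frame.
#' @param ages Numeric vector of ages at which to evaluate prevalence.
#' @return A data frame with columns `age`, `n`, `p1`, `p2`, `p3`
#'   (proportions summing to 1 wherever `n > 0`).
#' @export
prevalence_by_age <- function(panel, ages) {
  if (!inherits(panel, "smid_panel")) panel <- smid_panel(panel)
  Ab <- vapply(panel, `[[`, 0, "Ab")
  AN <- vapply(panel, `[[`, 0, "AN")
  dead <- vapply(panel, `[[`, TRUE, "dead")
  A20 <- vapply(panel, function(p) p$A20 %||% NA_real_, 0)
  out <- lapply(ages, function(a) {
    under <- Ab <= a & ((dead & AN <= a) | AN >= a)
    if (!any(under))
      return(data.frame(age = a, n = 0L, p1 = NA_real_, p2 = NA_real_,
                        p3 = NA_real_))
    st3 <- dead[under] & AN[under] <= a
    st2 <- !st3 & !is.na(A20[under]) & A20[under] <= a
    st1 <- !st3 & !st2
    n <- sum(under)
    data.frame(age = a, n = n, p1 = sum(st1) / n, p2 = sum(st2) / n,
               p3 = sum(st3) / n)
  })
  do.call(rbind, out)
}

#' Microsimulation goodness of fit
#'
#' Computes the observed Kaplan-Meier curve of survival after baseline for
#' the left-censored (E/F) individuals and the observed state-3 prevalence
#' over age, together with the pointwise envelope of the same summaries in
#' `R` microsimulated replicates of the cohort under the fitted model.
#'
#' @param fit A [smid] fit.
#' @param R Number of replicates.
#' @param seed Integer seed.
#' @param ages Age grid for the prevalence comparison (default: observed
#'   age range in 1-year steps).
#' @return A list of class `smid_gof`: `km_obs`, `km_sim` (list of
#'   replicate curves), `prev_obs`, `prev_sim`, `R`.
#' @export
smid_gof <- function(fit, R = 100, seed = NULL, ages = NULL) {
  panel <- fit$data
  pat <- patterns_of(panel)
  Ab <- vapply(panel, `[[`, 0, "Ab")
  AN <- vapply(panel, `[[`, 0, "AN")
  dead <- vapply(panel, `[[`, TRUE, "dead")
  if (is.null(ages)) {
    ages <- seq(floor(min(Ab)), ceiling(max(AN)), by = 1)
  }
  ef <- pat %in% c("E", "F")
  km_obs <- km_curve(AN[ef] - Ab[ef], as.integer(dead[ef]))
  prev_obs <- prevalence_by_age(panel, ages)
  sims <- microsimulate_fitted(fit, R = R, seed = seed)
  km_sim <- lapply(sims, function(s) {
    sp <- smid_panel(s)
    sAb <- vapply(sp, `[[`, 0, "Ab")
    sAN <- vapply(sp, `[[`, 0, "AN")
    sdead <- vapply(sp, `[[`, TRUE, "dead")
    km_curve(sAN[ef] - sAb[ef], as.integer(sdead[ef]))
  })
  prev_sim <- lapply(sims, prevalence_by_age, ages = ages)
  structure(list(km_obs = km_obs, km_sim = km_sim, prev_obs = prev_obs,
                 prev_sim = prev_sim, R = R, ages = ages),
            class = "smid_gof")
}

#' @export
plot.smid_gof <- function(x, which = c("km", "prevalence"), ...) {
  which <- match.arg(which)
  step_line <- function(d, col, lwd = 1, lty = 1)
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), col = col,
                    lwd = lwd, lty = lty, do.points = FALSE)
  if (which == "km") {
    graphics::plot(NA, xlim = c(0, max(c(x$km_obs$time, 1))), ylim = c(0, 1),
                   xlab = "years since baseline", ylab = "survival",
                   main = "Survival after baseline, left-censored individuals")
    for (d in x$km_sim) if (nrow(d)) step_line(d, col = "grey70", lty = 3)
    if (nrow(x$km_obs)) {
      step_line(x$km_obs, col = "black", lwd = 2)
      step_line(data.frame(time = x$km_obs$time, surv = x$km_obs$lower), "black", 1, 2)
      step_line(data.frame(time = x$km_obs$time, surv = x$km_obs$upper), "black", 1, 2)
    }
  } else {
    graphics::plot(x$prev_obs$age, x$prev_obs$p3, type = "l", lwd = 2,
                   ylim = c(0, 1), xlab = "age (years)",
                   ylab = "prevalence of death",
                   main = "Observed vs simulated state-3 prevalence")
    for (d in x$prev_sim)
      graphics::lines(d$age, d$p3, col = "grey70", lty = 3)
    graphics::lines(x$prev_obs$age, x$prev_obs$p3, lwd = 2)
  }
  invisible(x)
}

#' Simulate replicate cohorts from a fitted model
#'
#' `simulate()` method: microsimulation replicates cloned at the observed
#' baseline (see [microsimulate_fitted]).
#'
#' @param object A [smid] fit.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Passed to [microsimulate_fitted].
#' @return A list of panel data frames.
#' @export
simulate.smid <- function(object, nsim = 1, seed = NULL, ...) {
  microsimulate_fitted(object, R = nsim, seed = seed, ...)
}
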