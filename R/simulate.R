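# Piecewise-exponential trajectory simulation and the longitudinal study
# design (interval-censored illness, exact deaths, right censoring at the
# end of follow-up, left truncation of pre-baseline deaths).

#' True coefficients used by the built-in simulation scenarios
#'
#' @return A [smid_coef] with the `(1, A)` layout.
#' @export
scenario_theta <- function() {
  smid_coef(beta12 = c(-8.78, 0.065),
            beta13 = c(-10.31, 0.093),
            beta23 = c(-5.92, 0.052),
            gamma = -0.11)
}

#' Configuration of a simulation scenario
#'
#' Scenario I reflects moderate left censoring/truncation: all individuals
#' healthy at `A0 = 60`, baseline ages from N(65, 2) left-truncated at 64.
#' Scenario II reflects severe left censoring: `A0 = 40`, baseline ages
#' from N(75, 6.5) left-truncated at 64.
#' Both use a 2-year visit spacing over a 12-year follow-up, exact death
#' ages, a 0.25-year simulation resolution, 2500 simulated individuals of
#' whom the first 1500 alive at baseline are analysed.
#'
#' @param scenario `"I"`, `"II"` or `"custom"`.
#' @param A0 Age at which everyone starts healthy.
#' @param ab_mean,ab_sd,ab_min Baseline-age normal law and left-truncation
#'   bound (years).
#' @param n_pool Number of simulated individuals.
#' @param n_keep Number of analysed individuals (survivors at baseline).
#' @param followup Follow-up length (years).
#' @param spacing Visit spacing (years).
#' @param h Simulation resolution for the piecewise-constant intensities.
#' @param theta True coefficients ([smid_coef]).
#' @return A list of class `smid_scenario`.
#' @export
scenario_config <- function(scenario = c("I", "II", "custom"),
                            A0 = NULL, ab_mean = NULL, ab_sd = NULL,
                            ab_min = 64, n_pool = 2500, n_keep = 1500,
                            followup = 12, spacing = 2, h = 0.25,
                            theta = scenario_theta()) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    I = list(A0 = 60, ab_mean = 65, ab_sd = 2),
    II = list(A0 = 40, ab_mean = 75, ab_sd = 6.5),
    custom = list(A0 = A0, ab_mean = ab_mean, ab_sd = ab_sd))
  A0 <- A0 %||% defaults$A0
  ab_mean <- ab_mean %||% defaults$ab_mean
  ab_sd <- ab_sd %||% defaults$ab_sd
  if (is.null(A0) || is.null(ab_mean) || is.null(ab_sd))
    stop("custom scenarios need A0, ab_mean and ab_sd")
  stopifnot(n_keep <= n_pool, followup > 0, spacing > 0, h > 0)
  structure(list(scenario = scenario, A0 = A0, ab_mean = ab_mean,
                 ab_sd = ab_sd, ab_min = ab_min, n_pool = n_pool,
                 n_keep = n_keep, followup = followup, spacing = spacing,
                 h = h, theta = theta),
            class = "smid_scenario")
}

# truncated-normal draw by rejection (cheap at these parameters)
rtruncnorm_left <- function(n, mean, sd, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

# invert a piecewise-constant cumulative hazard: rates[k] on pieces of
# common width h starting at `start`; returns the event time for standard-
# exponential draw e, or NA if the event falls beyond the grid
invert_pch <- function(e, rates, start, h) {
  cum <- c(0, cumsum(rates * h))
  K <- length(rates)
  k <- findInterval(e, cum, left.open = FALSE)
  if (k > K) return(NA_real_)
  start + (k - 1) * h + (e - cum[k]) / rates[k]
}

#' Simulate illness-death trajectories under piecewise-constant intensities
#'
#' Each individual starts healthy at `A0`. Within every subinterval of
#' width `h`, exponential waiting times under the left-limit intensities
#' drive the competing 1->2 / 1->3 exit (destination chosen proportional to
#' the instantaneous rates), and after onset the 2->3 intensity runs on the
#' sojourn clock from the exact simulated onset age. Exact event ages are
#' retained.
#'
#' @param theta A [smid_coef] (no extra covariates).
#' @param n Number of trajectories.
#' @param A0 Starting (healthy) age.
#' @param horizon Age(s) past which simulation stops (scalar or length-n).
#' @param h Resolution of the piecewise-constant intensities (years).
#' @return A data frame with columns `W` (onset age, NA if never ill before
#'   `horizon`) and `death` (death age, NA if alive at `horizon`).
#' @export
simulate_trajectories <- function(theta, n, A0, horizon, h = 0.25) {
  horizon <- rep_len(horizon, n)
  hmax <- max(horizon)
  K <- ceiling((hmax - A0) / h + 1e-9)
  a <- A0 + (seq_len(K) - 1) * h
  q12 <- intensity_1j(theta, a, 2)
  q13 <- intensity_1j(theta, a, 3)
  lam1 <- q12 + q13
  cum1 <- c(0, cumsum(lam1 * h))

  e1 <- stats::rexp(n)
  k1 <- findInterval(e1, cum1)
  exit <- ifelse(k1 > K, NA_real_,
                 A0 + (pmin(k1, K) - 1) * h + (e1 - cum1[pmin(k1, K)]) / lam1[pmin(k1, K)])
  u <- stats::runif(n)
  to_ill <- !is.na(exit) & u < (q12[pmin(k1, K)] / lam1[pmin(k1, K)])

  W <- ifelse(to_ill & exit < horizon, exit, NA_real_)
  death <- ifelse(!to_ill & !is.na(exit) & exit < horizon, exit, NA_real_)

  s23 <- unname(theta$beta23[2L]); g <- theta$gamma
  e23 <- theta$beta23[1L]
  for (i in which(!is.na(W))) {
    K2 <- ceiling((horizon[i] - W[i]) / h + 1e-9)
    if (K2 < 1L) next
    a2 <- W[i] + (seq_len(K2) - 1) * h
    q23 <- exp(cap_lp(e23 + s23 * a2 + g * (a2 - W[i])))
    d <- invert_pch(stats::rexp(1L), q23, W[i], h)
    if (!is.na(d) && d < horizon[i]) death[i] <- d
  }
  data.frame(W = W, death = death)
}

#' Apply the longitudinal observation scheme to a simulated trajectory
#'
#' Visits at baseline and every `spacing` years up to `followup`; each
#' visit reports the current living state. Death ages are exact; an
#' individual alive at the end of follow-up is right censored there. An
#' onset between visits becomes interval-censored; an onset before baseline
#' yields baseline state 2 with the onset age hidden (left-censored).
#'
#' @param W,death Onset and death ages (NA when absent) for one individual.
#' @param Ab Baseline age; the individual must be alive at `Ab`.
#' @param followup,spacing Follow-up length and visit spacing (years).
#' @return A data frame of panel rows (`age`, `state`, `death`), or NULL if
#'   the individual died before baseline (left truncation).
#' @export
observe_trajectory <- function(W, death, Ab, followup = 12, spacing = 2) {
  if (!is.na(death) && death <= Ab) return(NULL)
  v <- Ab + seq(0, followup, by = spacing)
  v <- v[is.na(death) | v < death]
  st <- ifelse(!is.na(W) & v >= W, 2L, 1L)
  age <- v; state <- st; dth <- rep(0L, length(v))
  if (!is.na(death) && death <= Ab + followup) {
    age <- c(age, death); state <- c(state, 3L); dth <- c(dth, 1L)
  }
  data.frame(age = age, state = state, death = dth)
}

#' Generate a full scenario data set
#'
#' Draws baseline ages from the scenario's truncated normal, simulates
#' trajectories from `A0`, drops individuals dead before their baseline age
#' (left truncation), keeps the first `n_keep` survivors and applies the
#' observation scheme.
#'
#' @param config A [scenario_config].
#' @param seed Integer seed (all randomness flows from it).
#' @return A panel data frame (dialect of [smid_panel]) with attributes
#'   `design_stats` (fractions left-truncated and ill at baseline), `truth`
#'   (true onset/death ages of the analysed individuals) and `config`.
#' @examples
#' \donttest{
#' pan <- simulate_panel(scenario_config("I", n_pool = 500, n_keep = 300), seed = 7)
#' attr(pan, "design_stats")
#' }
#' @export
simulate_panel <- function(config, seed = NULL) {
  stopifnot(inherits(config, "smid_scenario"))
  if (!is.null(seed)) set.seed(seed)
  Ab <- rtruncnorm_left(config$n_pool, config$ab_mean, config$ab_sd, config$ab_min)
  traj <- simulate_trajectories(config$theta, config$n_pool, config$A0,
                                horizon = Ab + config$followup, h = config$h)
  truncated <- !is.na(traj$death) & traj$death <= Ab
  alive_idx <- which(!truncated)
  if (length(alive_idx) < config$n_keep)
    stop("fewer than n_keep individuals alive at baseline")
  keep <- alive_idx[seq_len(config$n_keep)]
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    d <- observe_trajectory(traj$W[i], traj$death[i], Ab[i],
                            config$followup, config$spacing)
    d$id <- j
    rows[[j]] <- d
  }
  out <- do.call(rbind, rows)[, c("id", "age", "state", "death")]
  ill_at_base <- !is.na(traj$W[keep]) & traj$W[keep] < Ab[keep]
  attr(out, "design_stats") <- list(
    frac_truncated = mean(truncated),
    frac_state2_baseline = mean(ill_at_base),
    n_pool = config$n_pool, n_keep = config$n_keep)
  attr(out, "truth") <- data.frame(id = seq_along(keep), Ab = Ab[keep],
                                   W = traj$W[keep], death = traj$death[keep])
  attr(out, "config") <- config
  out
}
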