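# Pattern classification, Simpson quadrature, per-pattern likelihood
# contributions and the total likelihood.

test_that("observation patterns are classified from the panel", {
  expect_equal(mixed_panel() |> smid:::patterns_of() |> unname(),
               c("A", "B", "C", "D", "E", "F"))
  # baseline death is rejected
  expect_error(smid_panel(data.frame(id = 1, age = 70, state = 3, death = 1)),
               "baseline state is death")
})

test_that("composite Simpson quadrature is exact on cubics and accurate", {
  for (res in c(0.5, 0.1, 0.037))
    expect_equal(simpson_integrate(function(x) x^3, 0, 1, res), 0.25)
  expect_equal(simpson_integrate(exp, 0, 1, 0.05), exp(1) - 1, tolerance = 1e-7)
  expect_identical(simpson_integrate(exp, 2, 2, 0.05), 0)
})

test_that("pattern A/B contributions behave at the structural limits", {
  pan <- mixed_panel()
  recA <- pan[[1]]; recB <- pan[[2]]
  st <- smid_settings(h = 0.25, int_res = 0.05)
  # q12 = 0 kills the A integrand entirely
  th_noill <- smid_coef(c(-100, 0), c(-3, 0), c(-2, 0), 0)
  expect_lt(likelihood_contribution(recA, th_noill, st), 1e-20)
  # no escape from state 2: B reduces to the onset-window mass, integral of
  # P11 q12 with P22 = 1
  th_stay <- smid_coef(c(-2, 0), c(-3, 0), c(-100, 0), 0)
  p11q12 <- function(w) {
    lam <- exp(-2) + exp(-3)
    exp(-lam * (w - recB$Ab)) * exp(-2)
  }
  expect_equal(likelihood_contribution(recB, th_stay, st),
               simpson_integrate(p11q12, recB$A1N, recB$A20, 0.01),
               tolerance = 1e-6)
  # a longer state-2 survival (more negative gamma) cannot decrease B
  th1 <- smid_coef(c(-2, 0), c(-3, 0), c(-1, 0.02), -0.05)
  th2 <- smid_coef(c(-2, 0), c(-3, 0), c(-1, 0.02), -0.40)
  expect_gte(likelihood_contribution(recB, th2, st),
             likelihood_contribution(recB, th1, st))
})

test_that("pattern C/D contributions have the stated two-branch structure", {
  pan <- mixed_panel()
  recC <- pan[[3]]; recD <- pan[[4]]
  st <- smid_settings()
  # q12 = 0: C collapses to P11 * q13(AN), D to P11
  th_noill <- smid_coef(c(-100, 0), c(log(0.05), 0), c(-2, 0), 0)
  expect_equal(likelihood_contribution(recC, th_noill, st),
               exp(-0.05 * (recC$AN - recC$Ab)) * 0.05, tolerance = 1e-10)
  expect_equal(likelihood_contribution(recD, th_noill, st),
               exp(-0.05 * (recD$AN - recD$Ab)), tolerance = 1e-10)
  # q13 = 0: C keeps only the unobserved-onset branch
  th_nodeath1 <- smid_coef(c(log(0.1), 0), c(-100, 0), c(log(0.2), 0), 0)
  lam1 <- 0.1 + exp(-100)
  branch <- simpson_integrate(function(w)
    exp(-lam1 * (w - recC$Ab)) * 0.1 * exp(-0.2 * (recC$AN - w)) * 0.2,
    recC$A1N, recC$AN, 0.01)
  expect_equal(likelihood_contribution(recC, th_nodeath1, st), branch,
               tolerance = 1e-6)
  # all rates ~0: D contributes 1
  th0 <- smid_coef(c(-100, 0), c(-100, 0), c(-100, 0), 0)
  expect_equal(likelihood_contribution(recD, th0, st), 1, tolerance = 1e-10)
})

test_that("constant-hazard contributions match a discrete-time chain oracle", {
  th <- const_theta(0.10, 0.05, 0.25)
  st <- smid_settings(h = 0.25, int_res = 0.01)
  # pattern D censored after the last healthy visit
  recD <- toy_record(c(70, 72, 74), c(1, 1, 1))[[1]]
  recD$AN <- 75.2  # vital status known 1.2y past the last interview
  oracle_D <- {
    P1 <- chain_probs(0.10, 0.05, 0.25, recD$A1N - recD$Ab)[1, 1]
    P2 <- chain_probs(0.10, 0.05, 0.25, recD$AN - recD$A1N)
    P1 * (P2[1, 1] + P2[1, 2])
  }
  expect_equal(likelihood_contribution(recD, th, st), oracle_D,
               tolerance = 1e-3)
  # pattern C: healthy visits then an exact death
  recC <- toy_record(c(70, 72), c(1, 1), death_age = 73.4)[[1]]
  oracle_C <- {
    P1 <- chain_probs(0.10, 0.05, 0.25, recC$A1N - recC$Ab)[1, 1]
    tau <- recC$AN - recC$A1N
    P2 <- chain_probs(0.10, 0.05, 0.25, tau)
    P1 * (P2[1, 1] * 0.05 + P2[1, 2] * 0.25)
  }
  expect_equal(likelihood_contribution(recC, th, st), oracle_C,
               tolerance = 1e-3)
  # pattern A: onset interval then an exact death
  recA <- toy_record(c(70, 72, 74), c(1, 1, 2), death_age = 75.5)[[1]]
  oracle_A <- {
    P1 <- chain_probs(0.10, 0.05, 0.25, recA$A1N - recA$Ab)[1, 1]
    P12 <- chain_probs(0.10, 0.05, 0.25, recA$A20 - recA$A1N)[1, 2]
    P22 <- exp(-0.25 * (recA$AN - recA$A20))
    P1 * P12 * P22 * 0.25
  }
  expect_equal(likelihood_contribution(recA, th, st), oracle_A,
               tolerance = 1e-3)
})

test_that("pattern E/F contributions match the closed-form Gompertz survivor", {
  # constant covariates: survivor over sojourn [Ab-W, AN-W] is
  # exp(-(alpha/xi) (exp(xi t1) - exp(xi t0)))
  th <- table2_theta()
  rec <- toy_record(c(68, 70, 72), c(2, 2, 2))[[1]]   # pattern F
  W <- 63.7
  g <- gompertz_sojourn(th, W)
  t0 <- rec$Ab - W; t1 <- rec$AN - W
  closed <- exp(-g$alpha23 / g$xi23 * (exp(g$xi23 * t1) - exp(g$xi23 * t0)))
  st <- smid_settings(h = 5e-4, int_res = 5e-4)   # fine grid: piecewise ~ exact
  expect_equal(likelihood_contribution(rec, th, st, W = W), closed,
               tolerance = 1e-5)
  # gamma = 0 removes all dependence on W
  th0 <- smid_coef(th$beta12, th$beta13, th$beta23, 0)
  v <- vapply(c(50, 55, 60), function(w)
    likelihood_contribution(rec, th0, smid_settings(), W = w), 0)
  expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  # no escape from state 2: F is 1, E is 0-rate-weighted
  recE <- toy_record(c(68, 70), c(2, 2), death_age = 71.8)[[1]]
  th_stay <- smid_coef(c(-2, 0), c(-3, 0), c(-100, 0), 0)
  expect_equal(likelihood_contribution(rec, th_stay, st, W = W), 1,
               tolerance = 1e-10)
  expect_lt(likelihood_contribution(recE, th_stay, st, W = W), 1e-20)
})

test_that("the vectorised likelihood equals the per-record contributions", {
  pan <- small_sim_panel(seed = 9)
  th <- table2_theta()
  st <- smid_settings(int_res = 0.1)
  pat <- smid:::patterns_of(pan)
  W <- ifelse(pat %in% c("E", "F"),
              vapply(pan, `[[`, 0, "Ab") - 2.5, NA_real_)
  literal <- -sum(log(vapply(seq_along(pan), function(i)
    likelihood_contribution(pan[[i]], th, st, W = W[i]), 0)))
  expect_equal(neg_log_likelihood(pan, th, st, W = W), literal,
               tolerance = 1e-10)
})

test_that("the total likelihood factorises over individuals", {
  pan <- small_sim_panel(seed = 5, n_keep = 60, n_pool = 150)
  th <- table2_theta()
  st <- smid_settings(int_res = 0.1)
  pat <- smid:::patterns_of(pan)
  W <- ifelse(pat %in% c("E", "F"), vapply(pan, `[[`, 0, "Ab") - 2, NA_real_)
  base <- neg_log_likelihood(pan, th, st, W = W)
  # permutation leaves the total unchanged exactly
  perm <- sample(seq_along(pan))
  pan_p <- smid:::subset_panel(pan, perm)
  expect_equal(neg_log_likelihood(pan_p, th, st, W = W[perm]), base)
  # duplicating every record doubles it
  pan_d <- smid:::subset_panel(pan, rep(seq_along(pan), 2))
  expect_equal(neg_log_likelihood(pan_d, th, st, W = rep(W, 2)), 2 * base)
  # empty panel contributes nothing
  expect_identical(neg_log_likelihood(smid:::subset_panel(pan, integer(0)), th, st), 0)
})

test_that("contributions converge in the integration resolution", {
  pan <- mixed_panel()
  th <- table2_theta()
  for (i in 1:4) {
    v1 <- likelihood_contribution(pan[[i]], th, smid_settings(int_res = 0.05))
    v2 <- likelihood_contribution(pan[[i]], th, smid_settings(int_res = 0.01))
    expect_equal(v1, v2, tolerance = 1e-5)
  }
})
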