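# Posterior of the left-censored onset age and the EM-inspired fit.

test_that("onset posterior normalises and respects support restrictions", {
  # crafted rates: transition possible only in subinterval 3
  K <- 6; wdt <- rep(0.25, K)
  q12 <- c(0, 0, 0.2, 0, 0, 0)
  lam1 <- q12 + 0.05
  P <- smid:::onset_posterior_probs(lam1, q12, wdt, ill_cumhaz = rep(0, K))
  expect_equal(P, c(0, 0, 1, 0, 0, 0))
  # model-based posterior sums to 1 within 1e-12 across random thetas
  rec <- toy_record(c(70, 72), c(2, 2))[[1]]
  set.seed(77)
  for (r in 1:20) {
    th <- smid_coef(c(rnorm(1, -8, 1), runif(1, 0, 0.1)),
                    c(rnorm(1, -10, 1), runif(1, 0, 0.1)),
                    c(rnorm(1, -6, 1), runif(1, 0, 0.1)),
                    runif(1, -0.2, 0.05))
    post <- onset_posterior(th, rec, A0 = 60, h = 0.25)
    expect_equal(sum(post$P), 1, tolerance = 1e-12)
    expect_true(all(post$P >= 0))
  }
})

test_that("age-constant posterior matches direct enumeration", {
  # constant rates, gamma = 0: P_k ~ exp(-lam1 (k-1) h) p12 exp(-q23 (K-k) h)
  th <- const_theta(0.08, 0.04, 0.3)
  rec <- toy_record(c(70, 72), c(2, 2))[[1]]
  h <- 0.25
  post <- onset_posterior(th, rec, A0 = 65, h = h)
  K <- post$grid$K
  lam1 <- 0.12
  p12 <- (0.08 / lam1) * (1 - exp(-lam1 * h))
  num <- vapply(1:K, function(k)
    exp(-lam1 * (k - 1) * h) * p12 * exp(-0.3 * (K - k) * h), 0)
  expect_equal(post$P, num / sum(num), tolerance = 1e-12)
})

test_that("expected subinterval is the floored multinomial mean", {
  expect_equal(expected_subinterval(c(0, 0, 0, 0, 1)), 5)
  expect_equal(expected_subinterval(rep(0.25, 4)), 2)  # floor(2.5)
  expect_equal(expected_subinterval(c(0.5, 0.5)), 1)   # floor(1.5)
})

test_that("expected within-subinterval time is the truncated-exponential mean", {
  expect_equal(expected_time_within(0, 0.25), 0.125)
  expect_equal(expected_time_within(1e-12, 0.4), 0.2)
  expect_equal(expected_time_within(10, 1000), 0.1, tolerance = 1e-6)
  # Monte-Carlo oracle at 1e6 draws
  set.seed(123)
  d <- stats::rexp(1e6, rate = 2)
  d <- d[d <= 1]
  mc_se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(expected_time_within(2, 1) - mean(d)), 3 * mc_se)
  # always inside (0, h)
  for (lam in c(0, 0.5, 5, 50))
    expect_true(expected_time_within(lam, 0.25) > 0 &&
                expected_time_within(lam, 0.25) < 0.25)
})

test_that("onset-age imputation arithmetic and bounds", {
  expect_equal(impute_onset_age(40, 1, 0.125, 0.25), 40.125)
  expect_equal(impute_onset_age(40, 100, 0.1, 0.25), 64.85)
  expect_warning(w <- impute_onset_age(60, 20, 0.2, 0.25, Ab = 64.5), "clamped")
  expect_lt(w, 64.5)
})

test_that("without left-censored records the EM degenerates to one fit", {
  pan <- small_sim_panel(seed = 21, n_keep = 80, n_pool = 200)
  keep <- which(smid:::patterns_of(pan) %in% c("A", "B", "C", "D"))
  pan_ad <- smid:::subset_panel(pan, keep)
  st <- smid_settings(int_res = 0.1, A0 = 60)
  fit_em <- smid(pan_ad, settings = st)
  fit_direct <- fit_mle(pan_ad, settings = st)
  expect_equal(fit_em$em_iterations, 0L)
  expect_identical(coef(fit_em), smid:::flatten_coef(fit_direct$theta))
  expect_equal(fit_em$loglik, fit_direct$loglik)
  expect_length(fit_em$W_imputed, 0)
})

test_that("EM fit imputes onsets inside (A0, Ab) and is deterministic", {
  pan <- small_sim_panel(seed = 31, n_keep = 100, n_pool = 220)
  st <- smid_settings(int_res = 0.1, A0 = 60)
  fit1 <- smid(pan, settings = st)
  fit2 <- smid(pan, settings = st)
  expect_identical(coef(fit1), coef(fit2))   # no randomness in E/M steps
  ef <- which(smid:::patterns_of(pan) %in% c("E", "F"))
  expect_gt(length(ef), 0)
  Ab <- vapply(pan[ef], `[[`, 0, "Ab")
  expect_true(all(fit1$W_imputed > 60 & fit1$W_imputed < Ab))
  # refitting from the optimum reproduces it (fixed point within tolerance)
  fit3 <- smid(pan, settings = st, theta0 = fit1$coefficients)
  expect_equal(coef(fit3), coef(fit1), tolerance = 1e-3)
})

test_that("imputed onset ages track the true hidden onsets", {
  # onsets hidden for E/F individuals: imputation should correlate
  # positively with the truth and have a small mean error when Ab - A0
  # is short
  cfg <- scenario_config("I", n_pool = 2200, n_keep = 1300)
  raw <- simulate_panel(cfg, seed = 55)
  pan <- smid_panel(raw)
  st <- smid_settings(int_res = 0.1, A0 = 60)
  fit <- smid(pan, settings = st)
  truth <- attr(raw, "truth")
  ef_ids <- as.integer(names(fit$W_imputed))
  trueW <- truth$W[match(ef_ids, truth$id)]
  expect_gt(length(ef_ids), 20)
  expect_gt(stats::cor(fit$W_imputed, trueW), 0.3)
  expect_lt(abs(mean(fit$W_imputed - trueW)), 1.5)
})
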