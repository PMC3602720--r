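# Independent oracles and fixture builders used across the test files.

# Discrete-time three-state chain with constant hazards (Markov case,
# gamma = 0): transition probabilities over duration t by stepping a small
# dt. Used as a brute-force oracle for the likelihood contributions.
chain_probs <- function(q12, q13, q23, t, dt = 1e-3) {
  P <- diag(3)
  Q <- matrix(c(-(q12 + q13), q12, q13,
                0, -q23, q23,
                0, 0, 0), 3, 3, byrow = TRUE)
  steps <- max(1L, round(t / dt))
  M <- diag(3) + Q * (t / steps)
  for (s in seq_len(steps)) P <- P %*% M
  P
}

# toy coefficient sets -------------------------------------------------------

# constant hazards (no age effect, Markov)
const_theta <- function(q12, q13, q23) {
  smid_coef(beta12 = c(log(q12), 0), beta13 = c(log(q13), 0),
            beta23 = c(log(q23), 0), gamma = 0)
}

table2_theta <- function() scenario_theta()

# record builders -------------------------------------------------------------

# build a single-record panel from visit ages/states (+ optional death age)
toy_record <- function(visit_age, visit_state, death_age = NA, id = 1) {
  df <- data.frame(id = id, age = visit_age, state = visit_state, death = 0L)
  if (!is.na(death_age))
    df <- rbind(df, data.frame(id = id, age = death_age, state = 3L, death = 1L))
  smid_panel(df)
}

# small mixed-pattern panel with known structure, deterministic
mixed_panel <- function() {
  rows <- rbind(
    data.frame(id = 1, age = c(65, 67, 69), state = c(1, 1, 2), death = 0),   # B
    data.frame(id = 1, age = 70.5, state = 3, death = 1),                     # -> A
    data.frame(id = 2, age = c(66, 68, 70), state = c(1, 1, 2), death = 0),   # B
    data.frame(id = 3, age = c(64, 66), state = c(1, 1), death = 0),          # C
    data.frame(id = 3, age = 67.2, state = 3, death = 1),
    data.frame(id = 4, age = c(65, 67, 69, 71), state = c(1, 1, 1, 1), death = 0), # D
    data.frame(id = 5, age = c(66, 68), state = c(2, 2), death = 0),          # E
    data.frame(id = 5, age = 69.3, state = 3, death = 1),
    data.frame(id = 6, age = c(65, 67, 69), state = c(2, 2, 2), death = 0))   # F
  smid_panel(rows)
}

# a simulated scenario panel small enough for fast fits
small_sim_panel <- function(seed = 42, scenario = "I", n_keep = 120,
                            n_pool = 250) {
  smid_panel(simulate_panel(scenario_config(scenario, n_pool = n_pool,
                                            n_keep = n_keep), seed = seed))
}

# hand product-limit estimator (oracle for km_curve)
km_oracle <- function(time, status) {
  o <- order(time)
  time <- time[o]; status <- status[o]
  ut <- unique(time[status == 1])
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & status == 1)
    n <- sum(time >= ut[i])
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}
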