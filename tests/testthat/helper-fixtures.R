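# Shared fixtures: the demonstration environment used throughout the
# learning-trajectory results (b = 2, c = 1, mu_A = -1, mu_B = 1,
# sigma = 1, rho = 0.6) and small helpers built in code.

demo_env <- function() {
  sdt_env("normal", mu_A = -1, mu_B = 1, sigma = 1, rho = 0.6,
          b = 2, c = 1)
}

# Accept-all history of n signallers from an environment.
accept_all_history <- function(env, n) {
  sample_signaller(env, n)
}

# Penalized negative log posterior of the logistic belief, written
# independently of the package internals (oracle for the MAP).
oracle_neg_post <- function(theta, x, y, prior_sd) {
  eta <- theta[1] + theta[2] * x
  -sum(y * eta - log1p(exp(eta))) + sum(theta^2) / (2 * prior_sd^2)
}

# Independent penalized-likelihood optimizer (BFGS, restarted until the
# solution stops moving).
oracle_map <- function(x, y, prior_sd) {
  fn <- function(th) oracle_neg_post(th, x, y, prior_sd)
  sol <- optim(c(0, 0), fn, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 1000))
  for (k in 1:3) {
    sol2 <- optim(sol$par, fn, method = "BFGS",
                  control = list(reltol = 1e-15, maxit = 1000))
    if (max(abs(sol2$par - sol$par)) < 1e-10) { sol <- sol2; break }
    sol <- sol2
  }
  sol$par
}

# Brute-force shortest interval covering `mass` of the points: exhaustive
# search over all candidate windows.
oracle_shortest_interval <- function(s, mass) {
  s <- sort(s)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- s[i]; hi <- s[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# Tiny two-volunteer choice log for likelihood and fitting fixtures.
tiny_choice_log <- function(n_trials = 10, seed = 42) {
  log <- generate_cohort(policy_spec("random"), treatment_spec("T4"), 2,
                         trembling_eps = 0.2, q = c(0.3, 0.8), seed = seed)
  log[log$trial <= n_trials, ]
}
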