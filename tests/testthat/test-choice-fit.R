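test_that("yoked probabilities honour history, ties and strategy definitions", {
  log <- tiny_choice_log(n_trials = 12)
  # random: every entry one half
  yr <- compute_yoked_probabilities(log, "random")
  expect_true(all(yr$value == 0.5))
  # greedy emits a hard 0/1 from the strict positive-payoff rule; at the
  # near-tied symmetric prior on trial 1 either side can fall out of the
  # Monte-Carlo estimate of the expected payoff, but never anything soft
  yg <- compute_yoked_probabilities(log, "greedy", b = 1, c = 1)
  expect_true(all(yg$value %in% c(0, 1)))
  # thompson first-trial probability is the prior tail, identical across
  # volunteers and strictly interior
  yt <- compute_yoked_probabilities(log, "thompson", b = 1, c = 1)
  t1 <- yt$value[yt$trial == 1]
  expect_true(all(t1 > 0 & t1 < 1))
  # determinism given the Monte-Carlo seed
  y2 <- compute_yoked_probabilities(log, "ucb", mc_seed = 5)
  y3 <- compute_yoked_probabilities(log, "ucb", mc_seed = 5)
  expect_identical(y2$value, y3$value)
  # softmax stores expected payoffs, not probabilities
  ys <- compute_yoked_probabilities(log, "softmax", b = 1, c = 1)
  expect_equal(attr(ys, "value_type"), "payoff")
  expect_true(all(abs(ys$value) <= 1))
  # a shuffled log is rejected
  bad <- log[rev(seq_len(nrow(log))), ]
  expect_error(compute_yoked_probabilities(bad, "random"), "increasing")
})

test_that("yoked replay reproduces the per-trial belief states", {
  log <- tiny_choice_log(n_trials = 12)
  yt <- compute_yoked_probabilities(log, "thompson", b = 1, c = 1)
  # manual oracle for one volunteer: replay acceptances and evaluate
  v <- log[log$volunteer_id == "v02", ]
  for (t in c(3, 9, 12)) {
    hist <- v[v$trial < t & v$accepted, ]
    bel <- logistic_belief(hist$x, hist$is_good)
    ref <- accept_probability(policy_spec("thompson"), belief = bel,
                              x = v$x[t], b = 1, c = 1)
    expect_equal(yt$value[yt$volunteer_id == "v02" & yt$trial == t], ref,
                 tolerance = 1e-12)
  }
})

test_that("the mixture likelihood matches a naive per-trial loop", {
  log <- tiny_choice_log(n_trials = 10)
  tab <- compute_yoked_probabilities(log, "thompson", b = 1, c = 1)
  eps <- 0.23
  q <- c(0.4, 0.7)
  got <- log_likelihood(tab, eps, q)
  # independent reimplementation: loop trial by trial
  ref <- 0
  vols <- unique(tab$volunteer_id)
  for (i in seq_len(nrow(tab))) {
    qi <- q[match(tab$volunteer_id[i], vols)]
    p <- eps * qi + (1 - eps) * tab$value[i]
    ref <- ref + if (tab$accepted[i]) log(p) else log(1 - p)
  }
  expect_lt(abs(got - ref), 1e-10)
  # softmax path converts stored payoffs through the temperature
  tabs <- compute_yoked_probabilities(log, "softmax", b = 1, c = 1)
  tau <- 0.4
  gots <- log_likelihood(tabs, eps, q, tau = tau)
  refs <- 0
  for (i in seq_len(nrow(tabs))) {
    qi <- q[match(tabs$volunteer_id[i], vols)]
    p <- eps * qi + (1 - eps) * plogis(tabs$value[i] / tau)
    refs <- refs + if (tabs$accepted[i]) log(p) else log(1 - p)
  }
  expect_lt(abs(gots - refs), 1e-10)
  expect_error(log_likelihood(tabs, eps, q), "tau")
})

test_that("degenerate mixtures reduce to their closed forms", {
  log <- tiny_choice_log(n_trials = 10)
  tab <- compute_yoked_probabilities(log, "random")
  # eps = 0 with the random strategy: every trial contributes log(1/2)
  expect_equal(log_likelihood(tab, 0, c(0.9, 0.1)),
               nrow(tab) * log(0.5))
  # eps = 1: pure Bernoulli(q_i) per volunteer
  q <- c(0.3, 0.8)
  acc <- tapply(tab$accepted, tab$volunteer_id, sum)
  tot <- tapply(tab$accepted, tab$volunteer_id, length)
  ref <- sum(acc * log(q) + (tot - acc) * log(1 - q))
  expect_equal(log_likelihood(tab, 1, q), ref, tolerance = 1e-12)
})

test_that("fitting recovers posterior structure and reports diagnostics", {
  set.seed(301)
  log <- generate_cohort(policy_spec("random"), treatment_spec("T4"), 6,
                         trembling_eps = 0.3, seed = 302)
  fit <- suppressWarnings(
    fit_choices(log, "random", n_iter = 1500, n_chains = 2,
                n_adapt = 200, mc_seed = 4))
  expect_s3_class(fit, "choice_fit")
  expect_equal(dim(fit$loglik), c(1500, 300))
  # posterior predictive acceptance rate tracks the empirical rate
  # (eps and q trade off for the random strategy, but their mixture
  # acceptance probability is identifiable)
  cm <- colMeans(fit$draws)
  qbar <- mean(plogis(fit$draws[, grep("^lq", colnames(fit$draws))]))
  pred <- mean(fit$draws[, "eps"]) * qbar +
    (1 - mean(fit$draws[, "eps"])) * 0.5
  expect_lt(abs(pred - mean(log$accepted)), 0.06)
  # summary and coefficients are well-formed
  s <- summary(fit)
  expect_true(all(c("eps", "sigma_q") %in% rownames(s$parameters)))
  expect_equal(unname(coef(fit)[["eps"]]), cm[["eps"]])
  expect_s3_class(logLik(fit), "logLik")
})

test_that("a prior-only fit returns the priors", {
  log <- tiny_choice_log(n_trials = 10)[0, ]
  fit <- fit_choices(log, "random", n_iter = 4000, n_chains = 2)
  expect_equal(mean(fit$draws[, "eps"]), 0.5, tolerance = 0.05)
  expect_equal(mean(fit$draws[, "sigma_q"]), 1, tolerance = 0.1)
  expect_null(fit$psis)
})

test_that("model comparison is reflexive, normalised and order-correct", {
  log <- tiny_choice_log(n_trials = 15)
  f1 <- suppressWarnings(
    fit_choices(log, "random", n_iter = 1200, n_chains = 2,
                n_adapt = 200, mc_seed = 8))
  f2 <- suppressWarnings(
    fit_choices(log, "thompson", n_iter = 1200, n_chains = 2,
                n_adapt = 200, mc_seed = 8))
  # comparing a model with itself: zero difference, equal weights
  self <- psis_compare(list(a = f1, b = f1))
  expect_equal(self$dPSIS, c(0, 0))
  expect_equal(self$weight, c(0.5, 0.5))
  cmp <- psis_compare(list(random = f1, thompson = f2))
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(cmp$PSIS))
  expect_equal(cmp$dPSIS[1], 0)
  expect_gt(cmp$dSE[2], 0)
  # mismatched trial sets are refused
  f3 <- suppressWarnings(
    fit_choices(tiny_choice_log(n_trials = 8), "random",
                n_iter = 1200, n_chains = 2, n_adapt = 200))
  expect_error(psis_compare(list(f1, f3)), "identical trial set")
})

test_that("softmax fitting is unaffected by the Monte-Carlo seeds of other tables", {
  log <- tiny_choice_log(n_trials = 10)
  a <- compute_yoked_probabilities(log, "softmax", mc_seed = 1)
  b <- compute_yoked_probabilities(log, "softmax", mc_seed = 1)
  expect_identical(a$value, b$value)
  # the softmax table depends only on its own seed, not on any
  # thompson/ucb tables computed in between
  compute_yoked_probabilities(log, "ucb", mc_seed = 99)
  c2 <- compute_yoked_probabilities(log, "softmax", mc_seed = 1)
  expect_identical(a$value, c2$value)
})

test_that("a degenerate one-trial cohort fits without crashing", {
  log <- tiny_choice_log(n_trials = 1)
  fit <- suppressWarnings(
    fit_choices(log, "random", n_iter = 800, n_chains = 1,
                n_adapt = 100))
  expect_s3_class(fit, "choice_fit")
  expect_equal(ncol(fit$loglik), 2)
})
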