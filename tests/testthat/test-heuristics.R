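test_that("policy specification validates names and required parameters", {
  expect_error(policy_spec("softmax"), "tau")
  expect_error(policy_spec("eps_greedy"), "eps_dither")
  expect_error(policy_spec("ucb", gamma = 1.5), "gamma")
  expect_error(policy_spec("bandito"), "valid names")
  # field abbreviations resolve to the same policies
  expect_equal(policy_spec("TS")$name, "thompson")
  expect_equal(policy_spec("SOFT", tau = 0.1)$name, "softmax")
  expect_equal(policy_spec("RDM")$name, "random")
  expect_equal(policy_spec("MID")$name, "midpoint")
  expect_equal(policy_spec("EGR", eps_dither = 0.05)$name, "eps_greedy")
  expect_equal(policy_spec("GR")$name, "greedy")
  expect_equal(policy_spec("SDT")$name, "sdt_oracle")
})

test_that("softmax follows the Boltzmann closed form and its limits", {
  # degenerate posterior at a known p via zero covariance
  bel <- function(p) sdtbandit:::new_belief(
    c(alpha = qlogis(p), beta = 0), matrix(0, 2, 2), 10, 10L)
  # v = 0 gives one half at every temperature
  for (tau in c(0.01, 0.1, 1, 100))
    expect_equal(accept_probability(policy_spec("softmax", tau = tau),
                                    belief = bel(0.5), x = 0, b = 1, c = 1),
                 0.5)
  # p = 0.75, b = c = 1, tau = 0.1: logistic(5)
  expect_equal(accept_probability(policy_spec("softmax", tau = 0.1),
                                  belief = bel(0.75), x = 0, b = 1, c = 1),
               plogis(5))
  # tau -> 0 approaches Greedy; tau -> Inf approaches Random
  g <- accept_probability(policy_spec("greedy"), belief = bel(0.75),
                          x = 0, b = 1, c = 1)
  expect_lt(abs(accept_probability(policy_spec("softmax", tau = 1e-4),
                                   belief = bel(0.75), x = 0, b = 1, c = 1) -
                  g), 1e-10)
  expect_lt(abs(accept_probability(policy_spec("softmax", tau = 1e6),
                                   belief = bel(0.75), x = 0, b = 1, c = 1) -
                  0.5), 1e-3)
})

test_that("thompson probability equals draw enumeration and the normal tail", {
  # enumeration over an explicit 3-draw posterior: one of three exceeds 1/2
  p <- accept_probability(policy_spec("thompson"), x = 0, b = 1, c = 1,
                          p_draws = c(0.1, 0.4, 0.9))
  expect_equal(p, 1 / 3)
  # closed form is the tail of the Gaussian linear predictor
  set.seed(61)
  s <- accept_all_history(demo_env(), 100)
  b <- logistic_belief(s$x, s$is_A)
  x <- 0.4
  exact <- accept_probability(policy_spec("thompson"), belief = b, x = x,
                              b = 2, c = 1)
  lp <- coef(b)[1] + coef(b)[2] * x
  sd_lp <- sqrt(drop(c(1, x) %*% vcov(b) %*% c(1, x)))
  expect_equal(exact, unname(pnorm((lp - log(1 / 2)) / sd_lp)))
  # Monte-Carlo enumeration converges on the closed form
  set.seed(62)
  mc <- accept_probability(policy_spec("thompson"), x = x, b = 2, c = 1,
                           p_draws = posterior_p_samples(b, x, 40000))
  expect_lt(abs(mc - exact), 3 / sqrt(40000) + 0.01)
})

test_that("hard rules reject on an exact payoff tie", {
  bel <- function(p) sdtbandit:::new_belief(
    c(alpha = qlogis(p), beta = 0), matrix(0, 2, 2), 10, 10L)
  # expected payoff exactly zero: strict > 0 means reject
  expect_equal(accept_probability(policy_spec("greedy"), belief = bel(0.5),
                                  x = 0, b = 1, c = 1), 0)
  expect_equal(accept_probability(policy_spec("ucb"), belief = bel(0.5),
                                  x = 0, b = 1, c = 1), 0)
  # ucb with a degenerate posterior at p = 0.2 rejects
  expect_equal(accept_probability(policy_spec("ucb"), belief = bel(0.2),
                                  x = 0, b = 1, c = 1), 0)
  # greedy accepts when the expected payoff is positive
  expect_equal(accept_probability(policy_spec("greedy"), belief = bel(0.6),
                                  x = 0, b = 1, c = 1), 1)
})

test_that("eps-greedy interpolates between greedy and random", {
  bel <- sdtbandit:::new_belief(c(alpha = qlogis(0.8), beta = 0),
                                matrix(0, 2, 2), 10, 10L)
  args <- list(belief = bel, x = 0, b = 1, c = 1)
  g <- do.call(accept_probability, c(list(policy_spec("greedy")), args))
  e0 <- do.call(accept_probability,
                c(list(policy_spec("eps_greedy", eps_dither = 0)), args))
  e1 <- do.call(accept_probability,
                c(list(policy_spec("eps_greedy", eps_dither = 1)), args))
  eh <- do.call(accept_probability,
                c(list(policy_spec("eps_greedy", eps_dither = 0.4)), args))
  expect_equal(e0, g)
  expect_equal(e1, 0.5)
  expect_equal(eh, 0.6 * g + 0.4 * 0.5)
})

test_that("the midpoint rule bootstraps, splits at the running midpoint, and updates means", {
  mid <- midpoint_state()
  pol <- policy_spec("midpoint")
  # bootstrap phase accepts everything
  expect_equal(accept_probability(pol, mid = mid, x = 99, b = 1, c = 1), 1)
  mid <- update_midpoint(mid, 0.2, TRUE)
  expect_equal(mid$mean_d, 0.2)
  expect_true(is.na(mid$mean_u))
  expect_equal(accept_probability(pol, mid = mid, x = 99, b = 1, c = 1), 1)
  mid <- update_midpoint(mid, 0.8, FALSE)
  # midpoint 0.5, desirable side is low
  expect_equal(accept_probability(pol, mid = mid, x = 0.3, b = 1, c = 1), 1)
  expect_equal(accept_probability(pol, mid = mid, x = 0.7, b = 1, c = 1), 0)
  # the exact midpoint is accepted
  expect_equal(accept_probability(pol, mid = mid, x = 0.5, b = 1, c = 1), 1)
  # running mean arithmetic
  mid <- update_midpoint(mid, 0.4, TRUE)
  expect_equal(mid$mean_d, 0.3)
  # interleaved updates equal the batch mean
  set.seed(71)
  xs <- runif(50)
  types <- runif(50) < 0.5
  m <- midpoint_state()
  for (i in 1:50) m <- update_midpoint(m, xs[i], types[i])
  expect_equal(m$mean_d, mean(xs[types]), tolerance = 1e-12)
  expect_equal(m$mean_u, mean(xs[!types]), tolerance = 1e-12)
})

test_that("random and oracle policies ignore or use the environment correctly", {
  env <- demo_env()
  expect_equal(accept_probability(policy_spec("random"), x = 3, b = 1,
                                  c = 1), 0.5)
  xstar <- optimal_threshold(env)
  # accept below the optimal threshold (mu_A < mu_B), reject above
  expect_equal(accept_probability(policy_spec("sdt_oracle"), x = xstar - 0.1,
                                  b = env$b, c = env$c, env = env), 1)
  expect_equal(accept_probability(policy_spec("sdt_oracle"), x = xstar + 0.1,
                                  b = env$b, c = env$c, env = env), 0)
  expect_error(accept_probability(policy_spec("sdt_oracle"), x = 0,
                                  b = 1, c = 1), "environment")
})

test_that("belief policies are monotone in the cue under a negative slope", {
  set.seed(81)
  s <- accept_all_history(demo_env(), 150)
  b <- logistic_belief(s$x, s$is_A)
  expect_lt(coef(b)[["beta"]], 0)
  xs <- seq(-2, 2, by = 0.5)
  for (pol in list(policy_spec("thompson"), policy_spec("greedy"),
                   policy_spec("softmax", tau = 0.3))) {
    set.seed(82)
    probs <- vapply(xs, function(x)
      accept_probability(pol, belief = b, x = x, b = 2, c = 1,
                         n_draws = 4000), numeric(1))
    expect_true(all(diff(probs) <= 1e-3))
  }
})

test_that("the UCB accept region contains the greedy accept region", {
  set.seed(91)
  s <- accept_all_history(demo_env(), 60)
  b <- logistic_belief(s$x, s$is_A)
  for (x in seq(-1.5, 1.5, by = 0.25)) {
    set.seed(92)
    g <- accept_probability(policy_spec("greedy"), belief = b, x = x,
                            b = 2, c = 1, n_draws = 4000)
    set.seed(92)
    u <- accept_probability(policy_spec("ucb"), belief = b, x = x,
                            b = 2, c = 1, n_draws = 4000)
    expect_gte(u, g)
  }
})
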