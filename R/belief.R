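#' Logistic belief about P(type A | x), by quadratic approximation
#'
#' The receiver assumes the log odds of a signaller being desirable is
#' affine in its appearance and maintains a posterior over the logit
#' intercept and slope, summarised as a bivariate normal (Laplace)
#' approximation centred at the MAP. The belief is (re)fitted from scratch
#' to the full history of *accepted* signallers; rejections carry no
#' information and never enter the history.
#'
#' With an empty history the belief equals the prior: mean `(0, 0)`,
#' covariance `diag(prior_sd^2, prior_sd^2)`. Otherwise the MAP of the
#' Bernoulli-logistic likelihood plus independent `N(0, prior_sd^2)`
#' priors is found by damped Newton iteration started at `(0, 0)`, and the
#' covariance is the inverse negative Hessian of the log posterior at the
#' MAP. The normal prior keeps the posterior proper even under complete
#' separation.
#'
#' @param x Cue values of accepted signallers (may be empty).
#' @param is_A Logical, same length as `x`: was each accepted signaller
#'   desirable?
#' @param prior_sd Prior standard deviation of both logit parameters.
#'   The default `sqrt(10)` gives each parameter an `N(0, 10)`
#'   (mean-variance) prior, weakly informative on the logit scale.
#' @param max_iter,tol Newton iteration cap and gradient convergence
#'   tolerance (max absolute gradient component).
#'
#' @return An object of class `"logistic_belief"`: list with `mean`
#'   (named `alpha`, `beta`), `cov` (2x2), `prior_sd`, `n`.
#' @examples
#' b <- logistic_belief(c(-1.2, 0.3, 1.5), c(TRUE, TRUE, FALSE))
#' coef(b)
#' @export
logistic_belief <- function(x = numeric(), is_A = logical(), prior_sd = sqrt(10),
                            max_iter = 100L, tol = 1e-8) {
  stopifnot(length(x) == length(is_A), all(is.finite(x)), prior_sd > 0)
  y <- as.numeric(is_A)
  n <- length(x)
  prior_prec <- 1 / prior_sd^2
  if (n == 0L) {
    return(new_belief(c(alpha = 0, beta = 0),
                      diag(prior_sd^2, 2), prior_sd, 0L))
  }
  X <- cbind(1, x)
  theta <- c(0, 0)
  neg_post <- function(th) {
    eta <- X %*% th
    # -log lik: sum(log(1+exp(eta)) - y*eta), stable via log1p
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * prior_prec * sum(th^2)
  }
  f <- neg_post(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    p <- stats::plogis(eta)
    grad <- -drop(crossprod(X, y - p)) + prior_prec * theta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- p * (1 - p)
    H <- crossprod(X, X * w) + diag(prior_prec, 2)
    step <- solve(H, grad)
    # damp: halve until the objective does not increase
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      fc <- neg_post(cand)
      if (fc <= f + 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    theta <- cand
    f <- fc
  }
  if (!converged) {
    eta <- drop(X %*% theta)
    p <- stats::plogis(eta)
    grad <- -drop(crossprod(X, y - p)) + prior_prec * theta
    if (max(abs(grad)) >= sqrt(tol))
      stop(sprintf(paste0("belief MAP did not converge in %d iterations ",
                          "(max |gradient| = %.3g, n = %d)"),
                   max_iter, max(abs(grad)), n))
  }
  eta <- drop(X %*% theta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  H <- crossprod(X, X * w) + diag(prior_prec, 2)
  cov <- solve(H)
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- NULL
  new_belief(stats::setNames(as.numeric(theta), c("alpha", "beta")),
             cov, prior_sd, n)
}

new_belief <- function(mean, cov, prior_sd, n) {
  structure(list(mean = mean, cov = cov, prior_sd = prior_sd, n = n),
            class = "logistic_belief")
}

#' @export
print.logistic_belief <- function(x, ...) {
  cat(sprintf("Logistic belief (Laplace) from %d accepted signallers\n", x$n))
  cat(sprintf("  alpha = %.4g (sd %.3g), beta = %.4g (sd %.3g)\n",
              x$mean[1], sqrt(x$cov[1, 1]), x$mean[2], sqrt(x$cov[2, 2])))
  invisible(x)
}

#' @export
coef.logistic_belief <- function(object, ...) object$mean

#' @rdname logistic_belief
#' @param object A `logistic_belief`.
#' @param ... Unused.
#' @export
vcov.logistic_belief <- function(object, ...) object$cov

# Mean and sd of the Gaussian linear predictor alpha + beta * x.
linear_predictor <- function(belief, x) {
  v <- c(1, x)
  list(mean = sum(belief$mean * v),
       sd = sqrt(max(drop(v %*% belief$cov %*% v), 0)))
}

#' Draw posterior probabilities that a signaller is desirable
#'
#' Draws `(alpha, beta)` from the belief's bivariate normal and returns
#' `plogis(alpha + beta x)` per draw: samples from the posterior
#' distribution of `P(type A | x)`.
#'
#' @param belief A [logistic_belief()].
#' @param x Cue value (scalar).
#' @param n_draws Number of posterior draws.
#' @return Numeric vector of length `n_draws`, strictly inside (0, 1).
#' @export
posterior_p_samples <- function(belief, x, n_draws = 1000L) {
  stopifnot(inherits(belief, "logistic_belief"), n_draws >= 1L)
  lp <- linear_predictor(belief, x)
  stats::plogis(stats::rnorm(n_draws, lp$mean, lp$sd))
}

#' Mean posterior probability that a signaller is desirable
#'
#' By default the Monte-Carlo mean of the posterior `p` distribution,
#' honouring the curvature of the logistic transform; `method = "plugin"`
#' returns `plogis(alpha + beta x)` at the posterior mean parameters
#' (used where a likelihood must be smooth in few parameters).
#'
#' The Monte-Carlo estimate deliberately retains its sampling noise: at a
#' symmetric prior the expected payoff sits exactly on the accept/reject
#' boundary of the hard rules, and the jitter of the estimate is what lets
#' a Greedy receiver ever accept its first signaller. Smoothing it away
#' leaves Greedy permanently stuck rejecting (rejection being
#' uninformative), which is not how a sampling-based estimate of the mean
#' behaves.
#'
#' @inheritParams posterior_p_samples
#' @param method `"mc"` (default) or `"plugin"`.
#' @return A probability.
#' @export
mean_p <- function(belief, x, n_draws = 1000L, method = c("mc", "plugin")) {
  method <- match.arg(method)
  lp <- linear_predictor(belief, x)
  if (method == "plugin" || lp$sd == 0) return(stats::plogis(lp$mean))
  mean(stats::plogis(stats::rnorm(n_draws, lp$mean, lp$sd)))
}

#' Shortest interval containing a given mass of a sample
#'
#' Sorts the sample and scans all windows spanning `ceiling(mass * n)`
#' points, returning the narrowest (the empirical highest-density
#' interval).
#'
#' @param samples Numeric vector.
#' @param mass Coverage in (0, 1).
#' @return Named vector `c(lower, upper)`.
#' @export
shortest_interval <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1, length(samples) >= 1L)
  s <- sort(samples)
  n <- length(s)
  m <- min(n, max(1L, ceiling(mass * n)))
  if (m == n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

#' Upper end of the highest-density interval of P(type A | x)
#'
#' The optimistic probability used by the UCB policy: the upper endpoint of
#' the shortest interval containing a proportion `1 - gamma` of the
#' posterior `p` samples at cue `x`.
#'
#' @inheritParams posterior_p_samples
#' @param gamma One minus the interval mass (default 0.05, a 95% HPDI).
#' @return A probability.
#' @export
hpdi_upper <- function(belief, x, gamma = 0.05, n_draws = 1000L) {
  stopifnot(gamma > 0, gamma < 1)
  lp <- linear_predictor(belief, x)
  if (lp$sd == 0) return(stats::plogis(lp$mean))
  shortest_interval(posterior_p_samples(belief, x, n_draws),
                    1 - gamma)[["upper"]]
}

#' Appearance threshold below (or above) which acceptance is profitable
#'
#' Solves `plogis(alpha + beta x) = c / (b + c)` at the posterior-mean
#' parameters: the cue value where the believed expected payoff of
#' acceptance crosses zero. This is the learned analogue of
#' [optimal_threshold()] and the statistic summarised across replicate
#' simulations.
#'
#' @inheritParams posterior_p_samples
#' @param b,c Acceptance payoffs.
#' @return The threshold, or `NA` if the believed slope is exactly zero.
#' @export
profit_threshold <- function(belief, b, c) {
  stopifnot(inherits(belief, "logistic_belief"))
  beta <- belief$mean[["beta"]]
  if (beta == 0) return(NA_real_)
  (log(c / b) - belief$mean[["alpha"]]) / beta
}
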