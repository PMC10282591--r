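#' Define a generative signal-detection environment
#'
#' An environment holds the two overlapping appearance distributions of
#' desirable (type A) and undesirable (type B) signallers, the base rate of
#' type A, and the payoffs of acceptance. Two classical families are
#' supported: the normal-normal equal-variance model and the power-law
#' model with negative-exponential appearance distributions. In both, the
#' log odds of a signaller being type A is an affine function of its
#' appearance `x`, which is what makes a logistic belief the natural
#' learner for the problem.
#'
#' @param family `"normal"` or `"exponential"`.
#' @param mu_A,mu_B Mean appearance of desirable (A) and undesirable (B)
#'   signallers, in cue units. Must differ; the exponential family requires
#'   both positive.
#' @param sigma Common standard deviation of the appearance distributions
#'   (normal family only).
#' @param rho Base rate: prior probability that an encountered signaller is
#'   type A, in (0, 1).
#' @param b Benefit of accepting a type A signaller (`> 0`).
#' @param c Cost of accepting a type B signaller (`> 0`); rejection always
#'   pays 0.
#' @param truncation Optional `c(lo, hi)` interval; sampled cues falling
#'   outside are clamped to the nearest bound.
#'
#' @return An object of class `"sdt_env"`.
#' @examples
#' env <- sdt_env("normal", mu_A = -1, mu_B = 1, sigma = 1,
#'                rho = 0.6, b = 2, c = 1)
#' optimal_threshold(env)
#' @export
sdt_env <- function(family = c("normal", "exponential"), mu_A, mu_B,
                    sigma = NULL, rho, b, c, truncation = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(mu_A), is.numeric(mu_B), length(mu_A) == 1L,
            length(mu_B) == 1L, is.finite(mu_A), is.finite(mu_B))
  if (mu_A == mu_B)
    stop("mu_A and mu_B must differ: equal means carry no cue information")
  if (family == "normal") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("the normal family requires sigma > 0")
  } else {
    if (mu_A <= 0 || mu_B <= 0)
      stop("the exponential family requires mu_A > 0 and mu_B > 0")
    sigma <- NULL
  }
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("rho must lie strictly between 0 and 1")
  if (!is.numeric(b) || b <= 0 || !is.numeric(c) || c <= 0)
    stop("payoffs b and c must be positive")
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || !all(is.finite(truncation)) ||
        truncation[1] >= truncation[2])
      stop("truncation must be c(lo, hi) with lo < hi")
  }
  structure(
    list(family = family, mu_A = mu_A, mu_B = mu_B, sigma = sigma,
         rho = rho, b = b, c = c, truncation = truncation),
    class = "sdt_env"
  )
}

#' @export
print.sdt_env <- function(x, ...) {
  cat("SDT environment (", x$family, " family)\n", sep = "")
  cat(sprintf("  mu_A = %g, mu_B = %g%s\n", x$mu_A, x$mu_B,
              if (x$family == "normal") sprintf(", sigma = %g", x$sigma) else ""))
  cat(sprintf("  base rate rho = %g, payoffs b = %g / -c = %g\n",
              x$rho, x$b, -x$c))
  if (!is.null(x$truncation))
    cat(sprintf("  cues clamped to [%g, %g]\n",
                x$truncation[1], x$truncation[2]))
  thr <- tryCatch(optimal_threshold(x), error = function(e) NA_real_)
  if (is.finite(thr))
    cat(sprintf("  optimal acceptance threshold x* = %.4g\n", thr))
  invisible(x)
}

#' Sample signallers from an environment
#'
#' Each signaller is type A with probability `rho`; its appearance is drawn
#' from the family distribution with the type-specific mean. Draws outside
#' a configured truncation interval are clamped to the nearest bound, so
#' the number of draws per encounter is fixed.
#'
#' @param env An [sdt_env()].
#' @param n Number of signallers.
#' @return A data frame with columns `is_A` (logical) and `x` (cue value).
#'   Uses the current RNG state; call `set.seed()` beforehand for
#'   reproducibility.
#' @export
sample_signaller <- function(env, n = 1L) {
  stopifnot(inherits(env, "sdt_env"), n >= 1L)
  is_A <- stats::runif(n) < env$rho
  mu <- ifelse(is_A, env$mu_A, env$mu_B)
  x <- switch(env$family,
    normal = stats::rnorm(n, mean = mu, sd = env$sigma),
    exponential = stats::rexp(n, rate = 1 / mu)
  )
  if (!is.null(env$truncation))
    x <- pmin(pmax(x, env$truncation[1]), env$truncation[2])
  data.frame(is_A = is_A, x = x)
}

#' True log odds that a signaller is desirable
#'
#' Returns `log(rho f_A(x) / ((1 - rho) f_B(x)))`, the complete-information
#' posterior log odds of type A given appearance `x`. For both supported
#' families this is affine in `x`: the receiver's logistic model is
#' correctly specified.
#'
#' @inheritParams sample_signaller
#' @param x Cue value(s).
#' @return Numeric vector of log odds, same length as `x`.
#' @export
true_log_odds <- function(env, x) {
  stopifnot(inherits(env, "sdt_env"))
  base <- log(env$rho / (1 - env$rho))
  switch(env$family,
    normal = base + (env$mu_A - env$mu_B) * x / env$sigma^2 +
      (env$mu_B^2 - env$mu_A^2) / (2 * env$sigma^2),
    exponential = base + log(env$mu_B / env$mu_A) +
      x * (1 / env$mu_B - 1 / env$mu_A)
  )
}

#' True affine coefficients of the log odds
#'
#' Intercept and slope of [true_log_odds()] as a function of `x`; the
#' parameters a fully informed logistic belief would hold.
#'
#' @inheritParams sample_signaller
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
true_logit_coefficients <- function(env) {
  alpha <- true_log_odds(env, 0)
  beta <- true_log_odds(env, 1) - alpha
  c(alpha = alpha, beta = beta)
}

#' Optimal (complete-information) acceptance threshold
#'
#' The appearance `x*` at which the expected payoff of acceptance,
#' `P(A | x) b - (1 - P(A | x)) c`, equals zero; acceptance is profitable
#' on the `mu_A` side of `x*`. For the normal family this is the midpoint
#' of the two means plus `sigma^2 log(c (1 - rho) / (b rho)) / (mu_A - mu_B)`;
#' for the exponential family it is obtained by solving the affine log odds
#' for `log(c/b)`.
#'
#' @inheritParams sample_signaller
#' @return The threshold `x*` (cue units).
#' @examples
#' env <- sdt_env("normal", -1, 1, sigma = 1, rho = 0.6, b = 2, c = 1)
#' optimal_threshold(env)  # 0.549
#' @export
optimal_threshold <- function(env) {
  stopifnot(inherits(env, "sdt_env"))
  lc <- log(env$c * (1 - env$rho) / (env$b * env$rho))
  if (env$family == "normal") {
    (env$mu_A + env$mu_B) / 2 + env$sigma^2 * lc / (env$mu_A - env$mu_B)
  } else {
    # solve log(rho/(1-rho)) + log(mu_B/mu_A) + x (1/mu_B - 1/mu_A) = log(c/b)
    (log(env$c / env$b) - log(env$rho / (1 - env$rho)) -
       log(env$mu_B / env$mu_A)) / (1 / env$mu_B - 1 / env$mu_A)
  }
}

# Accept side: +1 if acceptance is profitable above the threshold
# (mu_A > mu_B), -1 if below. Never hard-coded "below".
accept_side <- function(env) {
  if (env$mu_A > env$mu_B) 1 else -1
}

#' Per-type acceptance probabilities at a threshold
#'
#' Probability mass of each type's appearance distribution on the accept
#' side of `threshold` (the `mu_A` side; equality at the threshold counts
#' as accept). These are the complete-information acceptance rates a
#' threshold user realises on encounter.
#'
#' @inheritParams sample_signaller
#' @param threshold Acceptance threshold; defaults to [optimal_threshold()].
#' @return Named numeric vector `c(p_accept_A, p_accept_B)`.
#' @export
sdt_acceptance_rates <- function(env, threshold = optimal_threshold(env)) {
  stopifnot(inherits(env, "sdt_env"), is.finite(threshold) || is.infinite(threshold))
  side <- accept_side(env)
  pr <- function(mu) {
    p_below <- switch(env$family,
      normal = stats::pnorm(threshold, mean = mu, sd = env$sigma),
      exponential = stats::pexp(threshold, rate = 1 / mu)
    )
    if (side < 0) p_below else 1 - p_below
  }
  c(p_accept_A = pr(env$mu_A), p_accept_B = pr(env$mu_B))
}

#' Expected per-encounter payoff of a threshold rule
#'
#' `rho b p_accept_A - (1 - rho) c p_accept_B` at the given threshold. At
#' the optimal threshold this is the complete-information benchmark used as
#' a reference line when comparing learning policies.
#'
#' @inheritParams sdt_acceptance_rates
#' @return Expected payoff per encounter.
#' @export
expected_sdt_payoff <- function(env, threshold = optimal_threshold(env)) {
  p <- sdt_acceptance_rates(env, threshold)
  env$rho * env$b * p[["p_accept_A"]] -
    (1 - env$rho) * env$c * p[["p_accept_B"]]
}
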