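#' Specify an acceptance policy
#'
#' A policy maps the receiver's current belief (and, for some rules, its
#' running type means or the true environment) and the cue value of the
#' signaller in front of it to a probability of accepting. The simulator
#' then draws the action from that probability, which for Thompson
#' sampling is equivalent in distribution to sampling one posterior value
#' and acting greedily on it.
#'
#' Policies and their field abbreviations:
#' \describe{
#'   \item{`thompson` (TS)}{accept with the posterior probability that the
#'     payoff of acceptance is positive.}
#'   \item{`greedy` (GR)}{accept iff the expected payoff
#'     `p_bar b - (1 - p_bar) c` is strictly positive.}
#'   \item{`eps_greedy` (EGR)}{Greedy with probability `1 - eps_dither`,
#'     otherwise accept at random (probability 0.5).}
#'   \item{`softmax` (SOFT)}{accept with probability
#'     `plogis(v / tau)` where `v` is the expected payoff; tends to Greedy
#'     as `tau -> 0` and to Random as `tau -> Inf`.}
#'   \item{`ucb` (UCB)}{accept iff the payoff at the upper end of the
#'     `1 - gamma` HPDI of `p` is strictly positive.}
#'   \item{`midpoint` (MID)}{accept everything until at least one
#'     desirable and one undesirable signaller have been accepted, then
#'     accept iff the cue is on the desirable side of the midpoint of the
#'     two running sample means (ties accept).}
#'   \item{`random` (RDM)}{accept with probability 0.5 regardless of cue.}
#'   \item{`sdt_oracle` (SDT)}{complete information: accept iff the true
#'     expected payoff at `x` is strictly positive.}
#' }
#'
#' @param name Policy name or field abbreviation (case-insensitive).
#' @param tau Softmax temperature (> 0; required for `softmax`).
#' @param eps_dither Dithering rate in \[0, 1\] (required for
#'   `eps_greedy`).
#' @param gamma One minus the HPDI mass for `ucb` (default 0.05).
#' @return An object of class `"policy_spec"`.
#' @examples
#' policy_spec("SOFT", tau = 0.1)
#' policy_spec("thompson")
#' @export
policy_spec <- function(name, tau = NULL, eps_dither = NULL, gamma = 0.05) {
  canon <- c(thompson = "thompson", ts = "thompson",
             greedy = "greedy", gr = "greedy",
             eps_greedy = "eps_greedy", egr = "eps_greedy",
             softmax = "softmax", soft = "softmax",
             ucb = "ucb",
             midpoint = "midpoint", mid = "midpoint",
             random = "random", rdm = "random",
             sdt_oracle = "sdt_oracle", sdt = "sdt_oracle")
  key <- tolower(name)
  if (!key %in% names(canon))
    stop("unknown policy '", name, "'; valid names: ",
         paste(unique(canon), collapse = ", "),
         " (abbreviations TS, GR, EGR, SOFT, UCB, MID, RDM, SDT)")
  nm <- canon[[key]]
  if (nm == "softmax") {
    if (is.null(tau) || !is.numeric(tau) || tau <= 0)
      stop("softmax requires a temperature tau > 0")
  }
  if (nm == "eps_greedy") {
    if (is.null(eps_dither) || !is.numeric(eps_dither) ||
        eps_dither < 0 || eps_dither > 1)
      stop("eps_greedy requires eps_dither in [0, 1]")
  }
  if (nm == "ucb") {
    if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1)
      stop("ucb requires gamma in (0, 1)")
  }
  structure(list(name = nm, tau = tau, eps_dither = eps_dither,
                 gamma = gamma),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  pars <- switch(x$name,
    softmax = sprintf(" (tau = %g)", x$tau),
    eps_greedy = sprintf(" (eps = %g)", x$eps_dither),
    ucb = sprintf(" (gamma = %g)", x$gamma),
    "")
  cat("Acceptance policy: ", x$name, pars, "\n", sep = "")
  invisible(x)
}

# Does this policy consult the logistic belief at all?
policy_uses_belief <- function(policy) {
  policy$name %in% c("thompson", "greedy", "eps_greedy", "softmax", "ucb")
}

#' Running type means for the Midpoint policy
#'
#' Tracks the sample mean appearance of desirable and undesirable
#' signallers accepted so far. Means are `NA` until the first acceptance
#' of that type.
#'
#' @return An object of class `"midpoint_state"`.
#' @export
midpoint_state <- function() {
  structure(list(mean_d = NA_real_, n_d = 0L,
                 mean_u = NA_real_, n_u = 0L),
            class = "midpoint_state")
}

#' @rdname midpoint_state
#' @param mid A `midpoint_state`.
#' @param x Cue of the newly accepted signaller.
#' @param is_A Whether it turned out desirable.
#' @export
update_midpoint <- function(mid, x, is_A) {
  stopifnot(inherits(mid, "midpoint_state"))
  if (is_A) {
    mid$n_d <- mid$n_d + 1L
    mid$mean_d <- if (mid$n_d == 1L) x else
      mid$mean_d + (x - mid$mean_d) / mid$n_d
  } else {
    mid$n_u <- mid$n_u + 1L
    mid$mean_u <- if (mid$n_u == 1L) x else
      mid$mean_u + (x - mid$mean_u) / mid$n_u
  }
  mid
}

#' Probability that a policy accepts a signaller
#'
#' Evaluates the policy's acceptance probability at cue `x` given the
#' receiver's current state. Deterministic rules (Greedy, UCB, Midpoint,
#' SDT oracle) return exactly 0 or 1, with strict positivity of the
#' relevant payoff required to accept (an expected payoff of exactly zero
#' is rejected).
#'
#' The Thompson probability is computed in closed form: `p > c/(b+c)` iff
#' the Gaussian linear predictor exceeds `log(c/b)`, so the acceptance
#' probability is an exact normal tail. When an explicit vector of
#' posterior `p` draws is supplied via `p_draws`, Thompson, Greedy,
#' eps-Greedy and Softmax are instead evaluated by enumeration/averaging
#' over those draws (used for testing and for Monte-Carlo variants).
#'
#' @param policy A [policy_spec()].
#' @param belief A [logistic_belief()] (required by belief-using
#'   policies).
#' @param mid A [midpoint_state()] (Midpoint only).
#' @param x Cue value of the signaller.
#' @param b,c Acceptance payoffs.
#' @param env True environment (required by `sdt_oracle` only).
#' @param n_draws Monte-Carlo draws for `p_bar` / HPDI computations.
#' @param p_draws Optional explicit posterior `p` sample to use instead of
#'   fresh draws.
#' @return A probability in \[0, 1\].
#' @export
accept_probability <- function(policy, belief = NULL, mid = NULL, x,
                               b, c, env = NULL, n_draws = 1000L,
                               p_draws = NULL) {
  stopifnot(inherits(policy, "policy_spec"))
  cutoff <- c / (b + c)
  pbar <- function() {
    if (!is.null(p_draws)) mean(p_draws)
    else mean_p(belief, x, n_draws = n_draws)
  }
  switch(policy$name,
    random = 0.5,
    sdt_oracle = {
      if (is.null(env)) stop("sdt_oracle requires the true environment")
      p <- stats::plogis(true_log_odds(env, x))
      as.numeric(p * b - (1 - p) * c > 0)
    },
    midpoint = {
      if (is.null(mid)) stop("midpoint requires a midpoint_state")
      if (is.na(mid$mean_d) || is.na(mid$mean_u)) return(1)
      m <- (mid$mean_d + mid$mean_u) / 2
      if (mid$mean_d <= mid$mean_u) as.numeric(x <= m) else as.numeric(x >= m)
    },
    thompson = {
      if (!is.null(p_draws))
        return(mean(p_draws * b - (1 - p_draws) * c > 0))
      lp <- linear_predictor(belief, x)
      if (lp$sd == 0)
        return(as.numeric(lp$mean > log(c / b)))
      stats::pnorm((lp$mean - log(c / b)) / lp$sd)
    },
    greedy = {
      p <- pbar()
      as.numeric(p * b - (1 - p) * c > 0)
    },
    eps_greedy = {
      p <- pbar()
      g <- as.numeric(p * b - (1 - p) * c > 0)
      (1 - policy$eps_dither) * g + policy$eps_dither * 0.5
    },
    softmax = {
      p <- pbar()
      stats::plogis((p * b - (1 - p) * c) / policy$tau)
    },
    ucb = {
      pu <- if (!is.null(p_draws))
        shortest_interval(p_draws, 1 - policy$gamma)[["upper"]]
      else hpdi_upper(belief, x, gamma = policy$gamma, n_draws = n_draws)
      as.numeric(pu * b - (1 - pu) * c > 0)
    }
  )
}
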