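#' Experimental treatment presets
#'
#' The four factorial treatments of the greyness experiment: two levels of
#' discriminability of the signaller types times two base rates. Cues are
#' greyscale values `C` on \[0, 255\] (clamped), rescaled to `x = C / 255`
#' for all learning and fitting. High discriminability puts the desirable
#' and undesirable means at 90 and 165 (3 s.d. apart at sigma = 25); low
#' discriminability at 115 and 140 (1 s.d.). The base rate of a desirable
#' signaller is 0.7 (high) or 0.3 (low). Payoffs are +1 / -1 and each
#' volunteer faces 50 trials.
#'
#' Presets: `T1` = low discriminability + low base rate, `T2` = low + high,
#' `T3` = high + low, `T4` = high discriminability + high base rate.
#'
#' @param preset `"T1"`..`"T4"`, or `NULL` to use the two factors.
#' @param discriminability,base_rate `"low"` or `"high"` (ignored when
#'   `preset` is given).
#' @return An object of class `"treatment_spec"`: list with `name`,
#'   `discriminability`, `base_rate`, `env` (the cue-scale [sdt_env()] in
#'   `C` units, truncation \[0, 255\]), and `n_trials = 50`.
#' @examples
#' treatment_spec("T4")$env
#' @export
treatment_spec <- function(preset = NULL, discriminability = c("low", "high"),
                           base_rate = c("low", "high")) {
  if (!is.null(preset)) {
    lv <- switch(toupper(preset),
      T1 = c("low", "low"), T2 = c("low", "high"),
      T3 = c("high", "low"), T4 = c("high", "high"),
      stop("unknown treatment preset '", preset, "'; use T1..T4"))
    discriminability <- lv[1]
    base_rate <- lv[2]
  } else {
    discriminability <- match.arg(discriminability)
    base_rate <- match.arg(base_rate)
  }
  mus <- if (discriminability == "high") c(90, 165) else c(115, 140)
  rho <- if (base_rate == "high") 0.7 else 0.3
  name <- paste0("T", 1L + 2L * (discriminability == "high") +
                   (base_rate == "high"))
  structure(
    list(name = name, discriminability = discriminability,
         base_rate = base_rate,
         env = sdt_env("normal", mu_A = mus[1], mu_B = mus[2], sigma = 25,
                       rho = rho, b = 1, c = 1, truncation = c(0, 255)),
         n_trials = 50L),
    class = "treatment_spec"
  )
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat(sprintf("Treatment %s: %s discriminability, %s base rate\n",
              x$name, x$discriminability, x$base_rate))
  cat(sprintf("  mu_good = %g, mu_bad = %g, sigma = %g, rho = %g, %d trials\n",
              x$env$mu_A, x$env$mu_B, x$env$sigma, x$env$rho, x$n_trials))
  invisible(x)
}

# Rescale a C-unit treatment environment to the x = C/255 scale the
# receiver learns on. Clamping on C then dividing by 255 equals clamping
# x at the rescaled bounds, so the two runs are identical draw for draw.
rescale_env <- function(env, scale = 255) {
  sdt_env(env$family, mu_A = env$mu_A / scale, mu_B = env$mu_B / scale,
          sigma = if (is.null(env$sigma)) NULL else env$sigma / scale,
          rho = env$rho, b = env$b, c = env$c,
          truncation = if (is.null(env$truncation)) NULL
                       else env$truncation / scale)
}

#' Simulate one virtual volunteer with a trembling hand
#'
#' Runs the bandit loop of the greyness experiment for a single synthetic
#' volunteer following `policy`, with a trembling-hand deviation process:
#' on every trial the realised acceptance probability is
#' `trembling_eps * q + (1 - trembling_eps) * p_policy`. Belief and
#' midpoint state are updated from the decisions actually taken, so the
#' policy stays yoked to the volunteer's own history.
#'
#' @param volunteer_id Identifier written into the log.
#' @param policy A [policy_spec()].
#' @param treatment A [treatment_spec()].
#' @param trembling_eps Probability of deviating from the policy on a
#'   trial (default 0.1).
#' @param q This volunteer's acceptance probability when deviating.
#' @param prior_sd,n_draws Belief settings as in [run_episode()].
#' @param integer_cue Round the greyscale cue `C` to whole RGB levels
#'   after clamping (default `FALSE`: continuous cues keep the logistic
#'   model well-posed).
#' @return A choice-log data frame: one row per trial with columns
#'   `volunteer_id`, `treatment`, `trial`, `C`, `x`, `is_good`,
#'   `accepted`, `payoff`, `cum_payoff`. `x = C / 255` exactly. Uses the
#'   current RNG state.
#' @export
generate_volunteer <- function(volunteer_id, policy, treatment,
                               trembling_eps = 0.1, q = 0.5,
                               prior_sd = sqrt(10), n_draws = 1000L,
                               integer_cue = FALSE) {
  stopifnot(inherits(treatment, "treatment_spec"),
            inherits(policy, "policy_spec"),
            trembling_eps >= 0, trembling_eps <= 1, q >= 0, q <= 1)
  env_c <- treatment$env
  env_x <- rescale_env(env_c)
  n <- treatment$n_trials
  uses_belief <- policy_uses_belief(policy)
  belief <- logistic_belief(prior_sd = prior_sd)
  mid <- midpoint_state()
  hx <- numeric(0)
  hA <- logical(0)
  sig <- sample_signaller(env_c, n)
  C <- if (integer_cue) round(sig$x) else sig$x
  x <- C / 255
  accepted <- logical(n)
  payoff <- numeric(n)
  for (t in seq_len(n)) {
    p_pol <- accept_probability(policy, belief = belief, mid = mid,
                                x = x[t], b = env_x$b, c = env_x$c,
                                env = env_x, n_draws = n_draws)
    pr <- trembling_eps * q + (1 - trembling_eps) * p_pol
    acc <- stats::runif(1) < pr
    accepted[t] <- acc
    if (acc) {
      payoff[t] <- if (sig$is_A[t]) env_c$b else -env_c$c
      hx <- c(hx, x[t])
      hA <- c(hA, sig$is_A[t])
      if (uses_belief)
        belief <- logistic_belief(hx, hA, prior_sd = prior_sd)
      mid <- update_midpoint(mid, x[t], sig$is_A[t])
    }
  }
  data.frame(volunteer_id = volunteer_id, treatment = treatment$name,
             trial = seq_len(n), C = C, x = x, is_good = sig$is_A,
             accepted = accepted, payoff = payoff,
             cum_payoff = cumsum(payoff))
}

#' Simulate a cohort of virtual volunteers
#'
#' Generates `n_volunteers` independent volunteers under one treatment,
#' all following the same policy, each with its own deviation acceptance
#' probability `q_i`. Unless `q` is supplied, the `q_i` are drawn
#' logit-normal with mean 0 and a cohort-level s.d. drawn from
#' Exponential(1) -- the same hierarchy the fitting model assumes, so
#' recovery studies are well-specified.
#'
#' @inheritParams generate_volunteer
#' @param n_volunteers Cohort size (>= 1).
#' @param q Optional vector of deviation probabilities, recycled to
#'   `n_volunteers`; `NULL` to draw them hierarchically.
#' @param seed Seed for the whole cohort.
#' @return A choice-log data frame (`n_volunteers * n_trials` rows) with
#'   the columns of [generate_volunteer()].
#' @examples
#' log <- generate_cohort(policy_spec("softmax", tau = 0.37),
#'                        treatment_spec("T4"), n_volunteers = 2, seed = 1)
#' head(log)
#' @export
generate_cohort <- function(policy, treatment, n_volunteers,
                            trembling_eps = 0.1, q = NULL, seed = 1L,
                            prior_sd = sqrt(10), n_draws = 1000L,
                            integer_cue = FALSE) {
  stopifnot(n_volunteers >= 1L)
  set.seed(seed)
  qs <- if (is.null(q)) {
    sigma_q <- stats::rexp(1)
    stats::plogis(stats::rnorm(n_volunteers, 0, sigma_q))
  } else rep_len(q, n_volunteers)
  out <- vector("list", n_volunteers)
  for (i in seq_len(n_volunteers)) {
    out[[i]] <- generate_volunteer(
      volunteer_id = sprintf("v%02d", i), policy = policy,
      treatment = treatment, trembling_eps = trembling_eps, q = qs[i],
      prior_sd = prior_sd, n_draws = n_draws, integer_cue = integer_cue)
  }
  log <- do.call(rbind, out)
  attr(log, "q") <- qs
  attr(log, "trembling_eps") <- trembling_eps
  log
}
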