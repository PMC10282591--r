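#' Run one episode of the one-armed contextual bandit
#'
#' Presents the receiver with `n_encounters` signallers sampled from `env`.
#' At each encounter the acceptance probability is computed from the
#' *current* belief and midpoint state, the action is drawn Bernoulli from
#' it, and only on acceptance is the signaller's type revealed, the
#' history extended, and the belief refitted. Rejection pays 0 and
#' changes nothing: information flows through acceptances only.
#'
#' The belief is refitted from scratch after each acceptance (histories
#' are short, so repeated quadratic approximation is cheap), and only for
#' policies that consult it; for the others the final belief is fitted
#' once at the end so the learned profit threshold can still be reported.
#'
#' @param env An [sdt_env()].
#' @param policy A [policy_spec()].
#' @param n_encounters Number of encounters (>= 1).
#' @param prior_sd Prior s.d. of the logit parameters (default
#'   `sqrt(10)`: an `N(0, 10)` mean-variance prior on each).
#' @param n_draws Monte-Carlo draws behind `p_bar` / HPDI policies.
#' @return An object of class `"sdt_episode"`: list with `trials` (data
#'   frame `t`, `x`, `accept_prob`, `accepted`, `is_A`, `payoff`),
#'   `final_belief`, `final_threshold` (NA when the believed slope is 0),
#'   and `cumulative_payoff`. Uses the current RNG state.
#' @examples
#' set.seed(1)
#' env <- sdt_env("normal", -1, 1, sigma = 1, rho = 0.6, b = 2, c = 1)
#' ep <- run_episode(env, policy_spec("thompson"), 50)
#' ep
#' @export
run_episode <- function(env, policy, n_encounters, prior_sd = sqrt(10),
                        n_draws = 1000L) {
  stopifnot(inherits(env, "sdt_env"), inherits(policy, "policy_spec"),
            n_encounters >= 1L)
  uses_belief <- policy_uses_belief(policy)
  belief <- logistic_belief(prior_sd = prior_sd)
  mid <- midpoint_state()
  hx <- numeric(0)
  hA <- logical(0)
  sig <- sample_signaller(env, n_encounters)
  prob <- numeric(n_encounters)
  accepted <- logical(n_encounters)
  payoff <- numeric(n_encounters)
  for (t in seq_len(n_encounters)) {
    x <- sig$x[t]
    pr <- accept_probability(policy, belief = belief, mid = mid, x = x,
                             b = env$b, c = env$c, env = env,
                             n_draws = n_draws)
    acc <- stats::runif(1) < pr
    prob[t] <- pr
    accepted[t] <- acc
    if (acc) {
      is_A <- sig$is_A[t]
      payoff[t] <- if (is_A) env$b else -env$c
      hx <- c(hx, x)
      hA <- c(hA, is_A)
      if (uses_belief)
        belief <- logistic_belief(hx, hA, prior_sd = prior_sd)
      mid <- update_midpoint(mid, x, is_A)
    }
  }
  if (!uses_belief)
    belief <- logistic_belief(hx, hA, prior_sd = prior_sd)
  structure(
    list(trials = data.frame(t = seq_len(n_encounters), x = sig$x,
                             accept_prob = prob, accepted = accepted,
                             is_A = sig$is_A, payoff = payoff),
         final_belief = belief,
         final_threshold = profit_threshold(belief, env$b, env$c),
         cumulative_payoff = sum(payoff)),
    class = "sdt_episode"
  )
}

#' @export
print.sdt_episode <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("Bandit episode: %d encounters, %d accepted (%.2f)\n",
              n, sum(x$trials$accepted), mean(x$trials$accepted)))
  cat(sprintf("  cumulative payoff %g; learned profit threshold %s\n",
              x$cumulative_payoff,
              if (is.na(x$final_threshold)) "undefined (flat belief)"
              else sprintf("%.4g", x$final_threshold)))
  invisible(x)
}

#' Replicate episodes and aggregate the learning trajectory
#'
#' Runs `n_reps` independent episodes and aggregates the quantities used
#' to characterise a policy's learning: the per-encounter mean acceptance
#' probability conditioned on signaller type (the trajectory that should
#' approach the complete-information acceptance rates), the distribution
#' of learned profit thresholds at the end of the episode, and the mean
#' cumulative payoff with a 95% confidence interval.
#'
#' Each replicate runs on its own RNG substream derived from `seed`, so
#' any single replicate can be reproduced in isolation.
#'
#' @inheritParams run_episode
#' @param n_reps Number of replicate episodes.
#' @param seed Master seed for the replicate substreams.
#' @return An object of class `"sdt_replicates"`: list with
#'   `accept_prob_by_type` (data frame `t`, `mean_prob_A`, `mean_prob_B`),
#'   `thresholds` (vector, `NA` dropped; count reported in `n_flat`),
#'   `threshold_mean`, `threshold_sd`, `payoffs` (per-replicate cumulative
#'   payoffs), `payoff_mean`, `payoff_ci` (normal-theory 95% CI), and the
#'   call ingredients.
#' @export
run_replicates <- function(env, policy, n_encounters, n_reps, seed = 1L,
                           prior_sd = sqrt(10), n_draws = 1000L) {
  stopifnot(n_reps >= 1L)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  probA <- matrix(NA_real_, n_encounters, n_reps)
  probB <- matrix(NA_real_, n_encounters, n_reps)
  thresholds <- numeric(n_reps)
  payoffs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    ep <- run_episode(env, policy, n_encounters, prior_sd = prior_sd,
                      n_draws = n_draws)
    tr <- ep$trials
    probA[tr$t[tr$is_A], r] <- tr$accept_prob[tr$is_A]
    probB[tr$t[!tr$is_A], r] <- tr$accept_prob[!tr$is_A]
    thresholds[r] <- ep$final_threshold
    payoffs[r] <- ep$cumulative_payoff
  }
  thr <- thresholds[!is.na(thresholds)]
  pm <- mean(payoffs)
  pse <- stats::sd(payoffs) / sqrt(n_reps)
  structure(
    list(accept_prob_by_type = data.frame(
           t = seq_len(n_encounters),
           mean_prob_A = rowMeans(probA, na.rm = TRUE),
           mean_prob_B = rowMeans(probB, na.rm = TRUE)),
         thresholds = thr,
         n_flat = sum(is.na(thresholds)),
         threshold_mean = mean(thr),
         threshold_sd = stats::sd(thr),
         payoffs = payoffs,
         payoff_mean = pm,
         payoff_ci = c(lower = pm - 1.96 * pse, upper = pm + 1.96 * pse),
         env = env, policy = policy, n_encounters = n_encounters,
         n_reps = n_reps, seed = seed),
    class = "sdt_replicates"
  )
}

#' @export
print.sdt_replicates <- function(x, ...) {
  cat(sprintf("Replicated bandit runs: %d x %d encounters, policy %s\n",
              x$n_reps, x$n_encounters, x$policy$name))
  if (length(x$thresholds))
    cat(sprintf("  learned profit threshold: mean %.4g (sd %.3g, %d flat)\n",
                x$threshold_mean, x$threshold_sd, x$n_flat))
  cat(sprintf("  cumulative payoff: mean %.4g (95%% CI %.4g to %.4g)\n",
              x$payoff_mean, x$payoff_ci[1], x$payoff_ci[2]))
  invisible(x)
}
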