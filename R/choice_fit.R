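canonical_strategy <- function(name) {
  canon <- c(thompson = "thompson", ts = "thompson",
             greedy = "greedy", gr = "greedy",
             softmax = "softmax", soft = "softmax",
             ucb = "ucb",
             midpoint = "midpoint", mid = "midpoint",
             random = "random", rdm = "random",
             sdt_oracle = "sdt_oracle", sdt = "sdt_oracle")
  key <- tolower(name)
  if (!key %in% names(canon))
    stop("unknown strategy '", name, "'; valid: ",
         paste(unique(canon), collapse = ", "))
  canon[[key]]
}

validate_choice_log <- function(log) {
  need <- c("volunteer_id", "trial", "x", "is_good", "accepted")
  miss <- setdiff(need, names(log))
  if (length(miss))
    stop("choice log is missing columns: ", paste(miss, collapse = ", "))
  for (v in unique(log$volunteer_id)) {
    tr <- log$trial[log$volunteer_id == v]
    if (anyDuplicated(tr) || is.unsorted(tr, strictly = TRUE))
      stop("trials for volunteer '", v,
           "' must be strictly increasing and unique")
  }
  invisible(log)
}

#' Yoked policy acceptance probabilities for a choice log
#'
#' For every trial of every volunteer, rebuilds the belief (and midpoint
#' state) implied by that volunteer's *actual* acceptances on earlier
#' trials and evaluates the strategy at the trial's cue -- the strategy is
#' yoked to the volunteer's experience. For Softmax the stored value is
#' the expected payoff `v = p_bar b - (1 - p_bar) c` rather than a
#' probability, so the temperature can remain a free parameter inside the
#' sampler; all other strategies yield a fixed probability.
#'
#' Monte-Carlo draws behind `p_bar` and the UCB bound use `mc_seed`, so
#' the table is reproducible. The SDT-oracle strategy reads the treatment
#' name from the log and uses that treatment's true environment on the
#' rescaled cue.
#'
#' @param log A choice-log data frame (see [generate_cohort()]); rows
#'   ordered by volunteer and trial.
#' @param strategy Strategy name or abbreviation (`softmax`, `thompson`,
#'   `greedy`, `midpoint`, `ucb`, `sdt_oracle`, `random`).
#' @param b,c Acceptance payoffs assumed by the strategies (default the
#'   experiment's 1 and 1).
#' @param gamma UCB HPDI tail mass (fixed at 0.05 as in the fitted
#'   models).
#' @param prior_sd,n_draws Belief settings.
#' @param mc_seed Seed for the Monte-Carlo evaluations.
#' @return An object of class `"yoked_table"`: data frame with columns
#'   `volunteer_id`, `trial`, `accepted`, `value`, plus attributes
#'   `strategy`, `value_type` (`"prob"` or `"payoff"`), `b`, `c`.
#' @export
compute_yoked_probabilities <- function(log, strategy, b = 1, c = 1,
                                        gamma = 0.05, prior_sd = sqrt(10),
                                        n_draws = 1000L, mc_seed = 1L) {
  validate_choice_log(log)
  strategy <- canonical_strategy(strategy)
  policy <- switch(strategy,
    softmax = NULL,  # handled via stored payoff v
    policy_spec(strategy, gamma = gamma))
  set.seed(mc_seed)
  env <- NULL
  if (strategy == "sdt_oracle") {
    trt <- unique(log$treatment)
    if (length(trt) != 1L)
      stop("sdt_oracle yoking needs a single-treatment log")
    env <- rescale_env(treatment_spec(trt)$env)
  }
  out <- vector("list", length(unique(log$volunteer_id)))
  vols <- unique(log$volunteer_id)
  for (vi in seq_along(vols)) {
    rows <- log[log$volunteer_id == vols[vi], , drop = FALSE]
    n <- nrow(rows)
    belief <- logistic_belief(prior_sd = prior_sd)
    mid <- midpoint_state()
    hx <- numeric(0)
    hA <- logical(0)
    value <- numeric(n)
    for (t in seq_len(n)) {
      x <- rows$x[t]
      value[t] <- if (strategy == "softmax") {
        p <- mean_p(belief, x, n_draws = n_draws)
        p * b - (1 - p) * c
      } else {
        accept_probability(policy, belief = belief, mid = mid, x = x,
                           b = b, c = c, env = env, n_draws = n_draws)
      }
      if (rows$accepted[t]) {
        hx <- c(hx, x)
        hA <- c(hA, rows$is_good[t])
        if (strategy %in% c("thompson", "greedy", "softmax", "ucb"))
          belief <- logistic_belief(hx, hA, prior_sd = prior_sd)
        mid <- update_midpoint(mid, x, rows$is_good[t])
      }
    }
    out[[vi]] <- data.frame(volunteer_id = rows$volunteer_id,
                            trial = rows$trial,
                            accepted = rows$accepted, value = value)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(volunteer_id = character(), trial = integer(),
                      accepted = logical(), value = numeric())
  structure(tab, strategy = strategy,
            value_type = if (strategy == "softmax") "payoff" else "prob",
            b = b, c = c, class = c("yoked_table", "data.frame"))
}

#' Trembling-hand mixture log-likelihood of a yoked table
#'
#' The probability that volunteer `i` accepts on a trial is
#' `eps * q_i + (1 - eps) * p_strategy`: with probability `eps` the
#' volunteer deviates and accepts with its own probability `q_i`,
#' otherwise it follows the strategy. For a Softmax table the stored
#' expected payoff is converted via `plogis(v / tau)`. Log terms are
#' floored at `log(.Machine$double.xmin)` so an impossible outcome under
#' a degenerate mixture yields a finite, signalled floor rather than
#' `-Inf`.
#'
#' @param table A [compute_yoked_probabilities()] result.
#' @param eps Trembling probability in \[0, 1\].
#' @param q Deviation acceptance probabilities, one per volunteer (in
#'   order of first appearance, or named by volunteer id).
#' @param tau Softmax temperature (required for Softmax tables).
#' @param pointwise Return the per-trial vector instead of the sum.
#' @return The log-likelihood (or per-trial vector).
#' @export
log_likelihood <- function(table, eps, q, tau = NULL, pointwise = FALSE) {
  stopifnot(inherits(table, "yoked_table"), eps >= 0, eps <= 1)
  vols <- unique(table$volunteer_id)
  if (!is.null(names(q))) q <- q[vols]
  stopifnot(length(q) == length(vols), all(q >= 0), all(q <= 1))
  idx <- match(table$volunteer_id, vols)
  ps <- if (attr(table, "value_type") == "payoff") {
    if (is.null(tau) || tau <= 0)
      stop("a Softmax table needs a temperature tau > 0")
    stats::plogis(table$value / tau)
  } else table$value
  p <- eps * q[idx] + (1 - eps) * ps
  y <- as.numeric(table$accepted)
  ll <- y * log(p) + (1 - y) * log1p(-p)
  ll <- pmax(ll, log(.Machine$double.xmin))
  if (pointwise) ll else sum(ll)
}

jags_model_string <- function(softmax) {
  p_line <- if (softmax)
    "    p[t] <- eps * q[vol[t]] + (1 - eps) * ilogit(v[t] / tau)"
  else
    "    p[t] <- eps * q[vol[t]] + (1 - eps) * ps[t]"
  paste(c("model {",
          "  for (t in 1:N) {",
          p_line,
          "    y[t] ~ dbern(p[t])",
          "  }",
          "  for (i in 1:V) {",
          "    lq[i] ~ dnorm(0, pow(sigma_q, -2))",
          "    q[i] <- ilogit(lq[i])",
          "  }",
          "  eps ~ dunif(0, 1)",
          "  sigma_q ~ dexp(1)",
          if (softmax) "  tau ~ dexp(1)",
          "}"), collapse = "\n")
}

#' Fit a hierarchical trembling-hand choice model
#'
#' Fits, by MCMC, the mixture model in which each volunteer follows the
#' named strategy except on a fraction `eps` of trials where it accepts
#' with its own probability `q_i`. Priors: `eps ~ Uniform(0, 1)`,
#' `logit(q_i) ~ Normal(0, sigma_q)` with `sigma_q ~ Exponential(1)`, and
#' for Softmax `tau ~ Exponential(1)`; the strategies themselves assume
#' `Normal(0, 10)` belief priors on the logit intercept and slope.
#' Strategy acceptance probabilities are precomputed (yoked to each
#' volunteer's actual history); only the Softmax temperature remains
#' inside the sampler, via the stored expected payoffs.
#'
#' Sampling uses JAGS with `n_chains` chains of `n_iter` iterations each,
#' the first half discarded as warmup (both configurable). The pointwise
#' log-likelihood over the retained draws feeds [psis_loo()] for model
#' comparison.
#'
#' @inheritParams compute_yoked_probabilities
#' @param n_iter Iterations per chain, including warmup (default 4000).
#' @param n_chains Number of chains (default 4).
#' @param warmup_frac Fraction of each chain discarded (default 0.5).
#' @param n_adapt JAGS adaptation steps before warmup.
#' @param yoked Optional precomputed [compute_yoked_probabilities()]
#'   table (must match `strategy`).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"choice_fit"`: posterior `draws` matrix
#'   (`eps`, `sigma_q`, `q[i]`, `tau` if Softmax), pointwise `loglik`,
#'   `psis` ([psis_loo()] result), convergence `diagnostics` (split-chain
#'   R-hat and effective sample size), and the data bindings. A warning
#'   is issued (and recorded) if any R-hat exceeds 1.05.
#' @seealso [psis_compare()], [recovery_study()]
#' @export
fit_choices <- function(log, strategy, b = 1, c = 1, n_iter = 4000L,
                        n_chains = 4L, warmup_frac = 0.5, n_adapt = 500L,
                        gamma = 0.05, prior_sd = sqrt(10), n_draws = 1000L,
                        mc_seed = 1L, yoked = NULL, quiet = TRUE) {
  strategy <- canonical_strategy(strategy)
  if (is.null(yoked)) {
    yoked <- compute_yoked_probabilities(log, strategy, b = b, c = c,
                                         gamma = gamma, prior_sd = prior_sd,
                                         n_draws = n_draws,
                                         mc_seed = mc_seed)
  } else if (attr(yoked, "strategy") != strategy) {
    stop("yoked table was computed for strategy '",
         attr(yoked, "strategy"), "'")
  }
  vols <- unique(yoked$volunteer_id)
  vol_idx <- match(yoked$volunteer_id, vols)
  y <- as.numeric(yoked$accepted)
  n <- length(y)
  softmax <- identical(attr(yoked, "value_type"), "payoff")
  if (n == 0L) {
    # no data: the posterior is the prior; sample it directly
    s <- max(1L, (n_iter - floor(warmup_frac * n_iter)) * n_chains)
    set.seed(mc_seed)
    draws <- cbind(eps = stats::runif(s), sigma_q = stats::rexp(s))
    if (softmax) draws <- cbind(draws, tau = stats::rexp(s))
    return(structure(
      list(strategy = strategy, draws = draws,
           loglik = matrix(numeric(0), s, 0), psis = NULL,
           volunteers = character(0), y = numeric(0),
           vol_idx = integer(0), yoked = yoked, softmax = softmax,
           n_iter = n_iter, n_chains = n_chains,
           diagnostics = list(rhat = NULL, max_rhat = NA_real_,
                              ess = NULL, min_ess = NA_real_)),
      class = "choice_fit"))
  }
  data <- list(y = y, vol = vol_idx, N = n, V = length(vols))
  if (softmax) data$v <- yoked$value else data$ps <- yoked$value
  inits <- function(chain) {
    ini <- list(eps = 0.5, sigma_q = 1, lq = rep(0, length(vols)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = mc_seed * 1000L + chain)
    if (softmax) ini$tau <- 0.5
    ini
  }
  model <- rjags::jags.model(
    textConnection(jags_model_string(softmax)), data = data,
    inits = lapply(seq_len(n_chains), inits), n.chains = n_chains,
    n.adapt = n_adapt, quiet = quiet)
  n_warmup <- floor(warmup_frac * n_iter)
  update(model, n_warmup, progress.bar = "none")
  vars <- c("eps", "sigma_q", "lq", if (softmax) "tau")
  samp <- rjags::coda.samples(model, vars, n.iter = n_iter - n_warmup,
                              progress.bar = "none")
  diagnostics <- mcmc_diagnostics(samp)
  draws <- as.matrix(samp)
  # pointwise log-likelihood over retained draws
  lq_cols <- grep("^lq", colnames(draws))
  Q <- stats::plogis(draws[, lq_cols, drop = FALSE])
  eps <- draws[, "eps"]
  PS <- if (softmax) stats::plogis(outer(1 / draws[, "tau"], yoked$value))
        else matrix(yoked$value, nrow(draws), n, byrow = TRUE)
  P <- eps * Q[, vol_idx, drop = FALSE] + (1 - eps) * PS
  loglik <- log(ifelse(rep(y, each = nrow(P)) == 1, P, 1 - P))
  dim(loglik) <- dim(P)
  loglik <- pmax(loglik, log(.Machine$double.xmin))
  fit <- structure(
    list(strategy = strategy, draws = draws, loglik = loglik,
         psis = psis_loo(loglik), volunteers = vols, y = y,
         vol_idx = vol_idx, yoked = yoked, softmax = softmax,
         n_iter = n_iter, n_chains = n_chains,
         diagnostics = diagnostics),
    class = "choice_fit")
  if (isTRUE(diagnostics$max_rhat > 1.05))
    warning(sprintf("fit for '%s' may not have converged: max R-hat %.3f",
                    strategy, diagnostics$max_rhat))
  fit
}

mcmc_diagnostics <- function(samp) {
  rhat <- tryCatch({
    if (length(samp) > 1L)
      coda::gelman.diag(samp, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1]
    else NULL
  }, error = function(e) NULL)
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  list(rhat = rhat,
       max_rhat = if (is.null(rhat)) NA_real_ else max(rhat, na.rm = TRUE),
       ess = ess,
       min_ess = if (is.null(ess)) NA_real_ else min(ess))
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("Trembling-hand choice model: strategy %s, %d trials, %d volunteers\n",
              x$strategy, length(x$y), length(x$volunteers)))
  cm <- colMeans(x$draws)
  cat(sprintf("  posterior mean eps = %.3f, sigma_q = %.3f%s\n",
              cm[["eps"]], cm[["sigma_q"]],
              if (x$softmax) sprintf(", tau = %.3f", cm[["tau"]]) else ""))
  if (!is.null(x$psis))
    cat(sprintf("  PSIS deviance %.1f (se %.1f)", -2 * x$psis$elpd,
                2 * x$psis$se))
  else cat("  prior-only fit (no trials)")
  if (is.finite(x$diagnostics$max_rhat))
    cat(sprintf("; max R-hat %.3f", x$diagnostics$max_rhat))
  cat("\n")
  invisible(x)
}

#' @export
coef.choice_fit <- function(object, ...) {
  cm <- colMeans(object$draws)
  qm <- stats::plogis(cm[grep("^lq", names(cm))])
  names(qm) <- paste0("q[", object$volunteers, "]")
  c(cm[c("eps", "sigma_q", if (object$softmax) "tau")], qm)
}

#' @export
summary.choice_fit <- function(object, ...) {
  d <- object$draws
  tab <- t(apply(d, 2, function(col)
    c(mean = mean(col), sd = stats::sd(col),
      `2.5%` = unname(stats::quantile(col, 0.025)),
      `97.5%` = unname(stats::quantile(col, 0.975)))))
  res <- list(strategy = object$strategy, parameters = tab,
              psis = object$psis, diagnostics = object$diagnostics)
  class(res) <- "summary.choice_fit"
  res
}

#' @export
print.summary.choice_fit <- function(x, ...) {
  cat("Strategy:", x$strategy, "\n\nPosterior summary:\n")
  print(round(x$parameters, 4))
  cat("\n")
  if (!is.null(x$psis)) print(x$psis)
  if (is.finite(x$diagnostics$max_rhat))
    cat(sprintf("max R-hat %.3f, min ESS %.0f\n",
                x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

#' @export
logLik.choice_fit <- function(object, ...) {
  structure(object$psis$elpd, df = object$psis$p_loo,
            nobs = length(object$y), class = "logLik")
}

#' Compare fitted choice models by PSIS-LOO deviance
#'
#' Converts each fit's PSIS-LOO expected log predictive density to the
#' deviance scale (`-2 elpd`) and tabulates, ascending: deviance (`PSIS`)
#' and its SE, difference to the best model (`dPSIS`) with the SE of the
#' pointwise difference (`dSE`), effective parameter count (`pPSIS`), and
#' Akaike-style weights `exp(-dPSIS / 2)` normalised to 1.
#'
#' @param ... `choice_fit` objects (named, or a single named list). All
#'   fits must be of the identical trial set.
#' @return A data frame of class `"psis_compare"`, one row per model,
#'   sorted by deviance.
#' @export
psis_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "choice_fit"))
    fits <- fits[[1]]
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "choice_fit")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- make.unique(vapply(fits, `[[`, character(1), "strategy"))
  y0 <- fits[[1]]$y
  for (f in fits)
    if (!identical(f$y, y0))
      stop("all fits must be of the identical trial set")
  elpd_i <- vapply(fits, function(f) f$psis$pointwise,
                   numeric(length(y0)))
  dev <- -2 * colSums(elpd_i)
  se <- vapply(fits, function(f) 2 * f$psis$se, numeric(1))
  ord <- order(dev)
  best <- ord[1]
  d_dev <- dev - dev[best]
  d_se <- vapply(seq_along(fits), function(j) {
    if (j == best) 0
    else 2 * sqrt(length(y0) * stats::var(elpd_i[, j] - elpd_i[, best]))
  }, numeric(1))
  w <- exp(-0.5 * d_dev)
  w <- w / sum(w)
  out <- data.frame(model = names(fits), PSIS = dev, SE = se,
                    dPSIS = d_dev, dSE = d_se,
                    pPSIS = vapply(fits, function(f) f$psis$p_loo,
                                   numeric(1)),
                    weight = w, row.names = NULL)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("psis_compare", "data.frame")
  out
}

#' @export
print.psis_compare <- function(x, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Model-recovery study
#'
#' Repeatedly simulates cohorts of virtual volunteers that follow a known
#' generating strategy (with trembling-hand deviations), fits every
#' candidate trembling-hand model to each simulated cohort, and counts
#' how often PSIS-LOO comparison identifies the generating strategy as
#' best. This validates that the fitting pipeline can tell the candidate
#' heuristics apart at the experiment's sample sizes.
#'
#' @param strategy Generating strategy name.
#' @param treatment A [treatment_spec()] (default T4, high
#'   discriminability and high base rate).
#' @param n_sims Number of simulated cohorts.
#' @param n_volunteers Cohort size (default 8, the experiment's minimum
#'   per treatment).
#' @param trembling_eps Generating deviation rate (default 0.1).
#' @param tau Generating Softmax temperature (default 0.1, the
#'   temperature used for the simulated Softmax heuristic throughout).
#' @param candidates Candidate strategy set (default the seven fitted
#'   models).
#' @param n_iter,n_chains,n_adapt Sampler settings passed to
#'   [fit_choices()]; the defaults are reduced for study-size runs.
#' @param n_draws Monte-Carlo draws behind the yoked probabilities.
#' @param seed Master seed; each simulation gets its own substream.
#' @return An object of class `"recovery_study"`: list with `n_correct`,
#'   `fraction`, `identified` (best model per simulation), and `tables`
#'   (per-simulation comparison tables).
#' @export
recovery_study <- function(strategy = "softmax",
                           treatment = treatment_spec("T4"),
                           n_sims = 10L, n_volunteers = 8L,
                           trembling_eps = 0.1, tau = 0.1,
                           candidates = c("softmax", "thompson", "greedy",
                                          "midpoint", "ucb", "sdt_oracle",
                                          "random"),
                           n_iter = 2000L, n_chains = 2L, n_adapt = 300L,
                           n_draws = 1000L, seed = 1L) {
  strategy <- canonical_strategy(strategy)
  stopifnot(n_sims >= 1L)
  gen_policy <- if (strategy == "softmax")
    policy_spec("softmax", tau = tau)
  else policy_spec(strategy, eps_dither = 0.05)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sims)
  identified <- character(n_sims)
  tables <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    log <- generate_cohort(gen_policy, treatment, n_volunteers,
                           trembling_eps = trembling_eps,
                           seed = sim_seeds[s], n_draws = n_draws)
    fits <- lapply(candidates, function(cand)
      fit_choices(log, cand, b = treatment$env$b, c = treatment$env$c,
                  n_iter = n_iter, n_chains = n_chains, n_adapt = n_adapt,
                  n_draws = n_draws, mc_seed = sim_seeds[s] %% 100000L))
    names(fits) <- vapply(fits, `[[`, character(1), "strategy")
    tables[[s]] <- psis_compare(fits)
    identified[s] <- tables[[s]]$model[1]
  }
  structure(
    list(strategy = strategy, n_sims = n_sims,
         n_correct = sum(identified == strategy),
         fraction = mean(identified == strategy),
         identified = identified, tables = tables, seed = seed),
    class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Model recovery: generating strategy %s identified in %d/%d simulations\n",
              x$strategy, x$n_correct, x$n_sims))
  if (x$n_correct < x$n_sims)
    cat("  misidentified as:",
        paste(x$identified[x$identified != x$strategy], collapse = ", "),
        "\n")
  invisible(x)
}
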