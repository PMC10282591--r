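#' Read and write choice logs
#'
#' Choice logs are exchanged as comma-delimited text with a header and a
#' fixed column order (`volunteer_id`, `treatment`, `trial`, `C`, `x`,
#' `is_good`, `accepted`, `payoff`, `cum_payoff`). Numeric columns are
#' written with 17 significant digits so a write-read round trip is
#' lossless to the bit.
#'
#' @param log A choice-log data frame.
#' @param path File path.
#' @return `read_choice_log()` returns the data frame;
#'   `write_choice_log()` returns `path` invisibly.
#' @export
write_choice_log <- function(log, path) {
  cols <- c("volunteer_id", "treatment", "trial", "C", "x", "is_good",
            "accepted", "payoff", "cum_payoff")
  cols <- intersect(cols, names(log))
  out <- log[cols]
  for (nm in cols)
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choice_log
#' @export
read_choice_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("is_good", "accepted"))
    if (nm %in% names(log)) log[[nm]] <- as.logical(log[[nm]])
  for (nm in c("C", "x", "payoff", "cum_payoff"))
    if (nm %in% names(log)) log[[nm]] <- as.double(log[[nm]])
  validate_choice_log(log)
  log
}

config_keys <- c("environment", "treatment", "policy", "n_encounters",
                 "n_reps", "n_volunteers", "trembling_eps", "tau",
                 "eps_dither", "gamma", "seed", "out", "n_iter",
                 "n_chains", "strategy", "candidates", "n_sims",
                 "prior_sd", "n_draws")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a run: an environment (either a
#' `treatment` preset `T1`..`T4` or an `environment` mapping with keys
#' `family`, `mu_A`, `mu_B`, `sigma`, `rho`, `b`, `c`, `truncation`), a
#' `policy` name (full or field abbreviation) with its parameters, seeds,
#' sizes and output paths. Unknown keys are rejected by name. Presets and
#' policy abbreviations are expanded, so a loaded configuration carries
#' ready-to-use `sdt_env` / `policy_spec` objects.
#'
#' @param path Path to a YAML file.
#' @return An object of class `"run_config"`: the validated key-value
#'   list plus expanded `$env` and `$policy_spec` where applicable.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(config_keys, collapse = ", "))
  if (!is.null(cfg$treatment)) {
    cfg$treatment_spec <- treatment_spec(cfg$treatment)
    cfg$env <- cfg$treatment_spec$env
  } else if (!is.null(cfg$environment)) {
    e <- cfg$environment
    cfg$env <- sdt_env(family = e$family %||% "normal", mu_A = e$mu_A,
                       mu_B = e$mu_B, sigma = e$sigma, rho = e$rho,
                       b = e$b, c = e$c,
                       truncation = if (!is.null(e$truncation))
                         as.numeric(e$truncation))
  }
  if (!is.null(cfg$policy))
    cfg$policy_spec <- policy_spec(cfg$policy, tau = cfg$tau,
                                   eps_dither = cfg$eps_dither,
                                   gamma = cfg$gamma %||% 0.05)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param cfg A configuration list (raw keys only are written).
#' @export
save_config <- function(cfg, path) {
  keep <- intersect(names(cfg), config_keys)
  yaml::write_yaml(cfg[keep], path)
  invisible(path)
}

#' Write simulation or fitting results to disk
#'
#' Trial-level tables go to delimited text via [write_choice_log()] (or
#' `write.csv` for episode trials); aggregates -- replicate summaries,
#' comparison tables, fit summaries -- are serialised as JSON with
#' unboxed scalars. The JSON for an [run_replicates()] aggregate carries
#' the learned-threshold mean/sd, payoff mean/CI and the per-encounter
#' trajectories.
#'
#' @param object An `sdt_episode`, `sdt_replicates`, `psis_compare`,
#'   `recovery_study` or choice-log data frame.
#' @param path Output path (`.csv` or `.json` chosen by the writer).
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  if (inherits(object, "sdt_episode")) {
    utils::write.csv(object$trials, path, row.names = FALSE)
  } else if (inherits(object, "sdt_replicates")) {
    jsonlite::write_json(
      list(policy = object$policy$name,
           n_encounters = object$n_encounters, n_reps = object$n_reps,
           threshold_mean = object$threshold_mean,
           threshold_sd = object$threshold_sd,
           thresholds = object$thresholds, n_flat = object$n_flat,
           payoff_mean = object$payoff_mean,
           payoff_ci = as.list(object$payoff_ci),
           accept_prob_by_type = object$accept_prob_by_type),
      path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(object, "psis_compare")) {
    utils::write.csv(as.data.frame(object), path, row.names = FALSE)
  } else if (inherits(object, "recovery_study")) {
    jsonlite::write_json(
      list(strategy = object$strategy, n_sims = object$n_sims,
           n_correct = object$n_correct, fraction = object$fraction,
           identified = object$identified),
      path, auto_unbox = TRUE, digits = NA)
  } else if (is.data.frame(object)) {
    write_choice_log(object, path)
  } else stop("no writer for class ", paste(class(object), collapse = "/"))
  invisible(path)
}
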