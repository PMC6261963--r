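TRIAL_COLUMNS <- c("subject_id", "group", "day", "task_label", "block",
                   "trial_in_session", "pair_id", "better_on_left",
                   "chosen_better", "reward", "rt_ms")

#' Write a trial table (or cohort) to long-format CSV
#'
#' Booleans are serialized as 0/1 integers for portability; missing
#' responses stay empty fields.
#'
#' @param x an `rl_cohort` or a trial-table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  if (inherits(x, "rl_cohort")) x <- x$trials
  miss <- setdiff(TRIAL_COLUMNS, names(x))
  if (length(miss)) stop("trial table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- x[, TRIAL_COLUMNS]
  out$better_on_left <- as.integer(out$better_on_left)
  out$chosen_better <- as.integer(out$chosen_better)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a long-format trial table
#'
#' @param path CSV file.
#' @param column_map optional named character vector mapping the expected
#'   column names to the names used in the file, e.g.
#'   `c(subject_id = "id", reward = "feedback")`; unmapped columns must
#'   carry the expected names.
#' @return validated trial-table data.frame (logical columns restored).
#' @export
read_trials <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(d))
        stop("mapped column not in file: ", theirs, " (for ", ours, ")")
      names(d)[names(d) == theirs] <- ours
    }
  }
  miss <- setdiff(setdiff(TRIAL_COLUMNS, "rt_ms"), names(d))
  if (length(miss)) stop("file missing required columns: ",
                         paste(miss, collapse = ", "))
  if (!"rt_ms" %in% names(d)) d$rt_ms <- NA_real_
  d$rt_ms <- as.numeric(d$rt_ms)
  d$better_on_left <- as.logical(d$better_on_left)
  d$chosen_better <- as.logical(d$chosen_better)
  bad_group <- !d$group %in% RL_GROUPS
  if (any(bad_group))
    stop("invalid group values at rows: ",
         paste(utils::head(which(bad_group) + 1L, 5), collapse = ", "))
  bad_pair <- !d$pair_id %in% c("AB", "CD", "EF")
  if (any(bad_pair))
    stop("invalid pair_id values at rows: ",
         paste(utils::head(which(bad_pair) + 1L, 5), collapse = ", "))
  answered <- !is.na(d$chosen_better)
  bad_rew <- answered & (is.na(d$reward) | !d$reward %in% c(0L, 1L))
  if (any(bad_rew))
    stop("rewards must be 0/1 on answered trials; offending rows: ",
         paste(utils::head(which(bad_rew) + 1L, 5), collapse = ", "))
  key <- paste(d$subject_id, d$day, d$trial_in_session)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, day, trial_in_session) at rows: ",
         paste(utils::head(which(duplicated(key)) + 1L, 5), collapse = ", "))
  message(sprintf("read %d trials from %d subjects", nrow(d),
                  length(unique(d$subject_id))))
  d[, TRIAL_COLUMNS]
}

#' Read a run configuration from YAML
#'
#' The configuration bundles everything needed to regenerate a simulated
#' study: a cohort section (subject counts, generating hyperparameters
#' and effects, flags), a sampler section, the model variant and an
#' explicit seed.
#'
#' @param path YAML file.
#' @return list with elements `cohort` (a [cohort_spec()]), `sampler`
#'   (a [sampler_config()]), `variant` and `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("run config must state an explicit seed")
  hy <- do.call(hyper_params, as.list(y$cohort$hyper %||% list()))
  eff <- if (!is.null(y$cohort$effects)) {
    b <- unlist(y$cohort$effects$b)[RL_PARAMS]
    bg <- group_effects()$b_group
    for (g in names(y$cohort$effects$b_group %||% list()))
      bg[, g] <- unlist(y$cohort$effects$b_group[[g]])
    group_effects(b = b, b_group = bg)
  } else group_effects()
  npg <- unlist(y$cohort$n_per_group %||%
                  stats::setNames(rep(16L, 5), RL_GROUPS))
  cohort <- cohort_spec(n_per_group = npg, hyper = hy, effects = eff,
                        single_alpha = isTRUE(y$cohort$single_alpha),
                        share_days = isTRUE(y$cohort$share_days),
                        seed = y$seed)
  sampler <- do.call(sampler_config, as.list(y$sampler %||% list()))
  list(cohort = cohort, sampler = sampler,
       variant = y$variant %||% "M3_full", seed = as.integer(y$seed))
}

#' Write a run configuration to YAML
#'
#' @param config list as returned by [read_run_config()], or the pieces
#'   (`cohort`, `sampler`, `variant`, `seed`) assembled by hand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  co <- config$cohort
  y <- list(
    seed = config$seed,
    variant = config$variant,
    cohort = list(
      n_per_group = as.list(co$n_per_group),
      hyper = co$hyper[names(co$hyper)],
      effects = list(b = as.list(co$effects$b),
                     b_group = stats::setNames(
                       lapply(colnames(co$effects$b_group),
                              function(g) as.numeric(co$effects$b_group[, g])),
                       colnames(co$effects$b_group))),
      single_alpha = co$single_alpha,
      share_days = co$share_days),
    sampler = config$sampler[c("chains", "warmup", "iter")])
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
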