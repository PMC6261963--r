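#' Monte-Carlo map of expected task performance over parameter space
#'
#' For every grid cell, replicate agents with those parameters are run
#' through the session design and the mean proportion of better-symbol
#' choices is recorded. The map reproduces the familiar geometry of this
#' task: non-learning agents sit at chance, very noisy agents sit at
#' chance whatever their learning rates, and accuracy peaks at moderate
#' noise for learning agents.
#'
#' @param grid named list of exactly two numeric vectors from
#'   `alpha_G`, `alpha_L`, `beta` spanning the map axes.
#' @param fixed named list fixing the remaining parameter(s).
#' @param design the `session_design` to simulate (default: the 240-trial
#'   default task).
#' @param n_reps replicate agents per cell (>= 100 recommended).
#' @param n_schedules distinct randomized schedules shared across cells
#'   (common random numbers reduce between-cell noise).
#' @param seed integer seed.
#' @return a `performance_grid` data.frame with one row per cell and
#'   column `accuracy`.
#' @export
performance_map <- function(grid, fixed = list(),
                            design = make_design("task1_default"),
                            n_reps = 200L, n_schedules = 10L, seed = 1L) {
  stopifnot(is.list(grid), length(grid) == 2L,
            all(names(grid) %in% RL_PARAMS),
            all(lengths(grid) >= 1L))
  if (any(lengths(grid) == 0L) || any(!vapply(grid, is.numeric, logical(1))))
    stop("grid axes must be non-empty numeric vectors")
  missing_par <- setdiff(RL_PARAMS, c(names(grid), names(fixed)))
  if (length(missing_par))
    stop("parameter(s) neither on the grid nor fixed: ",
         paste(missing_par, collapse = ", "))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  with_preserved_seed(seed, {
    n_schedules <- min(n_schedules, n_reps)
    schedules <- lapply(seq_len(n_schedules), function(i)
      pair_index0(generate_session(design)$pair_id))
    reps_each <- diff(round(seq(0, n_reps, length.out = n_schedules + 1L)))
    acc <- vapply(seq_len(nrow(cells)), function(i) {
      par <- as.list(cells[i, , drop = FALSE])
      par <- utils::modifyList(par, fixed[setdiff(names(fixed), names(par))])
      w <- 0; tot <- 0
      for (j in seq_len(n_schedules)) {
        if (reps_each[j] == 0L) next
        a <- rl_sim_accuracy_cpp(schedules[[j]], design$pairs$p_better,
                                 design$pairs$p_worse,
                                 par$alpha_G, par$alpha_L, par$beta,
                                 reps_each[j])
        w <- w + a * reps_each[j]; tot <- tot + reps_each[j]
      }
      w / tot
    }, numeric(1))
    out <- cbind(cells, accuracy = acc)
    attr(out, "fixed") <- fixed
    attr(out, "design") <- design$task_label
    attr(out, "n_reps") <- n_reps
    class(out) <- c("performance_grid", "data.frame")
    out
  })
}

#' Scaled-down cohort specification for recovery studies
#'
#' Two groups (natural history and placebo) of 8 subjects with 120-trial
#' default sessions: small enough for desk-scale repeated fitting, while
#' keeping the structure (two days, manipulated day-1 task for the
#' placebo arm, day/group effects) of the full design. Reaction times and
#' subjective reports are disabled — they play no role in RL fitting.
#'
#' @param n_per_group named subject counts (default 8 + 8).
#' @param hyper,effects generating truth, see [hyper_params()],
#'   [group_effects()].
#' @param ... passed on to [cohort_spec()].
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
recovery_cohort_spec <- function(n_per_group = c(NHG = 8L, placebo = 8L),
                                 hyper = hyper_params(),
                                 effects = group_effects(), ...,
                                 seed = 1L) {
  short <- function(lab) {
    d <- make_design(lab)
    session_design(lab, n_blocks = 2L, reps_per_pair_per_block = 20L,
                   p_better = d$pairs$p_better, p_worse = d$pairs$p_worse)
  }
  cohort_spec(n_per_group = n_per_group, hyper = hyper, effects = effects,
              subjective_probs = NULL, rt = NULL,
              designs = list(task1_default = short("task1_default"),
                             task3_default = short("task3_default")),
              seed = seed, ...)
}

#' Parameter-recovery study: simulate, fit, compare to truth
#'
#' Each replicate simulates a cohort from known hyperparameters, fits the
#' requested model variant, and records for every group-level quantity
#' (means and day/group effects) the posterior mean, bias and whether the
#' 95% HDI covers the generating value, plus the rank correlation between
#' true and estimated subject-day parameters.
#'
#' By default the day and group effects of each replicate are freshly
#' drawn from centered normals (`effect_sd`, scales matching the
#' magnitude of effects this paradigm produces) rather than being fixed:
#' this is the simulation-based-calibration design under which 95% HDIs
#' are expected to cover the truth at their nominal rate when the
#' estimator is well calibrated. Set `effect_sd = NULL` to keep the
#' effects stored in `spec` for every replicate.
#'
#' @param spec generating `cohort_spec` (default: [recovery_cohort_spec()]).
#' @param n_replicates number of simulate-fit replicates.
#' @param variant model variant to fit.
#' @param config a [sampler_config()] (default desk-scale: 4 chains,
#'   400 warm-up, 400 retained each).
#' @param effect_sd named numeric `c(day = ..., group = ...)` giving the
#'   standard deviations from which each replicate's true day and group
#'   effects are drawn, or `NULL` to use `spec`'s fixed effects.
#' @param seed integer seed; replicate r simulates with `seed + 100 r`.
#' @return a `recovery_report`: `$per_parameter` (one row per replicate
#'   and group-level parameter), `$summary` (aggregated bias, RMSE,
#'   coverage), `$rank_cor` (per replicate and parameter), `$failures`.
#' @export
run_parameter_recovery <- function(spec = recovery_cohort_spec(),
                                   n_replicates = 3L,
                                   variant = "M3_full",
                                   config = sampler_config(chains = 4L,
                                                           warmup = 400L,
                                                           iter = 400L),
                                   effect_sd = c(day = 0.3, group = 0.2),
                                   seed = 1L) {
  stopifnot(n_replicates >= 1L)
  truth_of <- function(model, rspec) {
    h <- rspec$hyper; e <- rspec$effects
    if (model$variant == "M1_single_alpha")
      return(c(mu_alpha = h$mu_alphaG, mu_beta = h$mu_beta))
    if (model$variant == "M2_day_group") {
      tr <- c(mu_alpha = h$mu_alphaG, mu_beta = h$mu_beta,
              b_alpha = unname(e$b["alpha_G"]), b_beta = unname(e$b["beta"]))
      for (g in model$grp_levels)
        tr <- c(tr, stats::setNames(e$b_group[c("alpha_G", "beta"), g],
                                    paste0(c("b_alpha_", "b_beta_"), g)))
      return(tr)
    }
    tr <- c(mu_alphaG = h$mu_alphaG, mu_alphaL = h$mu_alphaL,
            mu_beta = h$mu_beta,
            stats::setNames(e$b[RL_PARAMS],
                            c("b_alphaG", "b_alphaL", "b_beta")))
    for (g in model$grp_levels)
      tr <- c(tr, stats::setNames(e$b_group[, g],
                                  paste0(c("b_alphaG_", "b_alphaL_",
                                           "b_beta_"), g)))
    tr
  }
  rows <- list(); rks <- list(); failures <- 0L
  for (r in seq_len(n_replicates)) {
    rspec <- spec; rspec$seed <- as.integer(seed + 100L * r)
    if (!is.null(effect_sd)) {
      rspec$effects <- with_preserved_seed(seed + 100L * r + 7L, {
        e <- spec$effects
        e$b[] <- stats::rnorm(3, 0, effect_sd[["day"]])
        e$b_group[] <- stats::rnorm(length(e$b_group), 0,
                                    effect_sd[["group"]])
        e
      })
    }
    cohort <- simulate_cohort(rspec)
    fit <- tryCatch(
      withCallingHandlers(
        fit_rl(build_model(cohort$trials, variant = variant),
               config = config, seed = seed + r),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) { failures <<- failures + 1L; NULL })
    if (is.null(fit)) next
    m <- as_draws_matrix(fit, natural_scales = FALSE)
    truth <- truth_of(fit$model, rspec)
    keep <- intersect(names(truth), colnames(m))
    rows[[r]] <- do.call(rbind, lapply(keep, function(nm) {
      h <- hdi(m[, nm])
      data.frame(replicate = r, parameter = nm, truth = truth[[nm]],
                 post_mean = mean(m[, nm]),
                 bias = mean(m[, nm]) - truth[[nm]],
                 covered = truth[[nm]] >= h[1] & truth[[nm]] <= h[2],
                 stringsAsFactors = FALSE)
    }))
    # subject-day rank correlation (true vs estimated, natural scale)
    nat <- fit$model$natural_params(
      m[unique(round(seq(1, nrow(m), length.out = min(200, nrow(m))))), ,
        drop = FALSE])
    truep <- cohort$true_params
    key <- paste(fit$model$data$subjects[rep(seq_along(fit$model$data$subjects),
                                             each = if (fit$model$variant ==
                                                        "M1_single_alpha") 1 else 2)],
                 if (fit$model$variant == "M1_single_alpha") 1L else
                   rep(1:2, length(fit$model$data$subjects)))
    tkey <- paste(truep$subject_id, truep$day)
    sel <- match(key, tkey)
    rks[[r]] <- data.frame(
      replicate = r,
      alpha_G = stats::cor(colMeans(nat$alpha_G),
                           to_natural(truep$alpha_G[sel]),
                           method = "spearman"),
      alpha_L = stats::cor(colMeans(nat$alpha_L),
                           to_natural(truep$alpha_L[sel]),
                           method = "spearman"),
      beta = stats::cor(colMeans(nat$beta),
                        to_natural_beta(truep$beta[sel]),
                        method = "spearman"))
  }
  per_par <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_par, per_par$parameter),
                                   function(d)
    data.frame(parameter = d$parameter[1],
               bias = mean(d$bias),
               rmse = sqrt(mean(d$bias^2)),
               coverage = mean(d$covered), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(per_parameter = per_par, summary = summary,
                 rank_cor = do.call(rbind, rks), failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over",
      length(unique(x$per_parameter$replicate)), "replicate(s); overall",
      sprintf("HDI coverage %.0f%%\n", 100 * mean(x$per_parameter$covered)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Model-recovery study: which variant wins LOOIC on known ground truth
#'
#' Simulates cohorts from either the full dual-learning-rate model (with
#' well-separated gain/loss rates) or the single-learning-rate model,
#' fits both M1 and M3 to every replicate, and records the LOOIC
#' difference (positive = full model preferred) and whether the
#' preference is strong (|delta| > 10).
#'
#' @param generating_variant `"M3_full"` or `"M1_single_alpha"`.
#' @param n_replicates replicates.
#' @param spec generating `cohort_spec`; by default a single-group
#'   8-subject cohort with 120-trial sessions, gain rate near 0.7 and
#'   loss rate near 0.2 under M3 generation, or one shared rate near 0.35
#'   under M1 generation.
#' @param config a [sampler_config()] for both fits.
#' @param seed integer seed.
#' @return data.frame per replicate: `looic_m1`, `looic_m3`,
#'   `delta_looic` (m1 minus m3), `winner`, `strong`.
#' @export
run_model_recovery <- function(generating_variant = c("M3_full",
                                                      "M1_single_alpha"),
                               n_replicates = 3L, spec = NULL,
                               config = sampler_config(chains = 4L,
                                                       warmup = 300L,
                                                       iter = 300L),
                               seed = 1L) {
  generating_variant <- match.arg(generating_variant)
  if (is.null(spec)) {
    spec <- if (generating_variant == "M3_full") {
      recovery_cohort_spec(
        n_per_group = c(NHG = 8L),
        hyper = hyper_params(mu_alphaG = stats::qnorm(0.7),
                             mu_alphaL = stats::qnorm(0.2),
                             mu_beta = -1.5,
                             sigma_alphaG = 0.2, sigma_alphaL = 0.2,
                             sigma_beta = 0.15),
        effects = group_effects(b = c(alpha_G = 0, alpha_L = 0, beta = 0)))
    } else {
      recovery_cohort_spec(
        n_per_group = c(NHG = 8L),
        hyper = hyper_params(mu_alphaG = stats::qnorm(0.35),
                             mu_alphaL = stats::qnorm(0.35),
                             mu_beta = -1.5,
                             sigma_alphaG = 0.2, sigma_alphaL = 0.2,
                             sigma_beta = 0.15),
        single_alpha = TRUE, share_days = TRUE)
    }
  }
  rows <- list()
  for (r in seq_len(n_replicates)) {
    rspec <- spec; rspec$seed <- as.integer(seed + 100L * r)
    cohort <- simulate_cohort(rspec)
    res <- tryCatch({
      quiet_fit <- function(variant)
        withCallingHandlers(
          fit_rl(build_model(cohort$trials, variant = variant),
                 config = config, seed = seed + r),
          warning = function(w) invokeRestart("muffleWarning"))
      f1 <- quiet_fit("M1_single_alpha")
      f3 <- quiet_fit("M3_full")
      l1 <- psis_loo(pointwise_matrix(f1, max_draws = 600L), warn = FALSE)
      l3 <- psis_loo(pointwise_matrix(f3, max_draws = 600L), warn = FALSE)
      data.frame(replicate = r, looic_m1 = l1$looic, looic_m3 = l3$looic,
                 delta_looic = l1$looic - l3$looic,
                 winner = if (l3$looic < l1$looic) "M3_full" else
                   "M1_single_alpha",
                 strong = abs(l1$looic - l3$looic) > 10,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (!is.null(res)) rows[[r]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "generating_variant") <- generating_variant
  out
}
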