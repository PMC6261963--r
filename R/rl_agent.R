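#' @useDynLib placeboRL, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RL_GROUPS <- c("NHG", "placebo", "nocebo", "placebo_control", "nocebo_control")
RL_PARAMS <- c("alpha_G", "alpha_L", "beta")

#' Parameters of a dual-learning-rate Q-learning agent
#'
#' @param alpha_G learning rate for gains (positive prediction errors),
#'   in \[0, 1\].
#' @param alpha_L learning rate for losses (negative prediction errors),
#'   in \[0, 1\].
#' @param beta exploration ("noise") parameter, > 0; the softmax uses
#'   exp(Q / beta), so larger beta makes choices more random.
#' @return an `agent_params` object.
#' @export
agent_params <- function(alpha_G, alpha_L, beta) {
  stopifnot(length(alpha_G) == 1L, length(alpha_L) == 1L, length(beta) == 1L)
  if (is.na(alpha_G) || alpha_G < 0 || alpha_G > 1)
    stop("alpha_G must be in [0, 1]")
  if (is.na(alpha_L) || alpha_L < 0 || alpha_L > 1)
    stop("alpha_L must be in [0, 1]")
  if (is.na(beta) || beta <= 0) stop("beta must be > 0")
  structure(list(alpha_G = alpha_G, alpha_L = alpha_L, beta = beta),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("RL agent: alpha_G = %.3f, alpha_L = %.3f, beta = %.3f\n",
              x$alpha_G, x$alpha_L, x$beta))
  invisible(x)
}

#' Rescorla-Wagner value update with separate gain/loss learning rates
#'
#' `q' = q + alpha_G (r - q)` when the prediction error `r - q` is
#' positive, `q' = q + alpha_L (r - q)` when it is negative, and `q` is
#' unchanged when it is exactly zero. Only the chosen symbol's value is
#' ever updated; callers pass that value. Vectorized over `q`/`reward`.
#'
#' @param q current value estimate(s), finite.
#' @param reward observed reward(s) in {0, 1}.
#' @param params an [agent_params()] object.
#' @return updated value(s).
#' @export
q_update <- function(q, reward, params) {
  stopifnot(inherits(params, "agent_params"), all(is.finite(q)),
            all(reward %in% c(0, 1)))
  pe <- reward - q
  q + ifelse(pe > 0, params$alpha_G * pe,
             ifelse(pe < 0, params$alpha_L * pe, 0))
}

#' Softmax choice probability
#'
#' Probability of choosing the symbol with value `q_a` over the one with
#' value `q_b`: `exp(q_a/beta) / (exp(q_a/beta) + exp(q_b/beta))`,
#' computed stably as a logistic of the scaled value difference.
#'
#' @param q_a,q_b action values.
#' @param beta exploration parameter, > 0.
#' @return probability of choosing `a`; vectorized.
#' @examples
#' choice_prob(0.8, 0.2, 2) # ~0.57: near-chance even with perfect knowledge
#' @export
choice_prob <- function(q_a, q_b, beta) {
  if (any(beta <= 0)) stop("beta must be > 0")
  stats::plogis((q_a - q_b) / beta)
}

#' Day-by-task schedule of each experimental group
#'
#' All groups perform the default 240-trial task on day 1 and again on
#' day 2; the four manipulated groups additionally perform the 120-trial
#' manipulated task at the end of day 1 (easier contingencies for the
#' placebo arm, harder for the nocebo arm).
#'
#' @param group one of `"NHG"`, `"placebo"`, `"nocebo"`,
#'   `"placebo_control"`, `"nocebo_control"`.
#' @return data.frame with columns `day` and `task_label` in session order.
#' @export
group_schedule <- function(group) {
  group <- match.arg(group, RL_GROUPS)
  task2 <- switch(group,
                  placebo = , placebo_control = "task2_placebo",
                  nocebo = , nocebo_control = "task2_nocebo",
                  NULL)
  day1 <- c("task1_default", task2)
  data.frame(day = c(rep(1L, length(day1)), 2L),
             task_label = c(day1, "task3_default"),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic reaction-time generator
#'
#' Reaction times are not part of the reinforcement-learning model; they
#' exist solely to exercise the reaction-time regression. Simulated RTs
#' are lognormal on the millisecond scale with optional additive log-scale
#' shifts for day 2 and per group, truncated at the response deadline.
#'
#' @param meanlog,sdlog lognormal parameters of the day-1 baseline.
#' @param day2_shift log-scale shift applied on day 2 (negative = faster).
#' @param group_shifts named numeric of extra day-2 log-scale shifts per
#'   group (missing groups get 0).
#' @param deadline_ms truncation point, ms.
#' @return an `rt_config` list.
#' @export
rt_config <- function(meanlog = log(750), sdlog = 0.25, day2_shift = -0.06,
                      group_shifts = c(placebo = -0.06), deadline_ms = 1700) {
  structure(list(meanlog = meanlog, sdlog = sdlog, day2_shift = day2_shift,
                 group_shifts = group_shifts, deadline_ms = deadline_ms),
            class = "rt_config")
}

simulate_rt <- function(n, day, group, rt) {
  shift <- if (day == 2L) {
    rt$day2_shift + if (group %in% names(rt$group_shifts))
      rt$group_shifts[[group]] else 0
  } else 0
  pmin(stats::rlnorm(n, rt$meanlog + shift, rt$sdlog), rt$deadline_ms)
}

#' Simulate one subject through their group's two-day schedule
#'
#' Choices are sampled from the softmax over the current Q values, rewards
#' from the session's contingencies, and Q is updated for the chosen
#' symbol only. Q is reset to zero at the start of every session (the
#' symbols of each task are distinct), and day-2 behavior uses the day-2
#' parameter set.
#'
#' @param params_day1,params_day2 [agent_params()] for each day.
#' @param group experimental group, see [group_schedule()].
#' @param seed optional integer for reproducibility.
#' @param designs optional named list of `session_design` objects keyed by
#'   task label, overriding the built-ins (e.g. shortened sessions).
#' @param rt an [rt_config()] or `NULL` to skip reaction times.
#' @return data.frame of trial records with columns `day`, `task_label`,
#'   `block`, `trial_in_session`, `pair_id`, `better_on_left`,
#'   `chosen_better`, `reward`, `rt_ms`.
#' @export
simulate_subject <- function(params_day1, params_day2, group, seed = NULL,
                             designs = NULL, rt = rt_config()) {
  stopifnot(inherits(params_day1, "agent_params"),
            inherits(params_day2, "agent_params"))
  group <- match.arg(group, RL_GROUPS)
  sched <- group_schedule(group)
  with_preserved_seed(seed, {
    sessions <- lapply(seq_len(nrow(sched)), function(i) {
      lab <- sched$task_label[i]
      design <- if (!is.null(designs) && lab %in% names(designs))
        designs[[lab]] else make_design(lab)
      par <- if (sched$day[i] == 1L) params_day1 else params_day2
      trials <- generate_session(design)
      sim <- rl_simulate_cpp(match(trials$pair_id, c("AB", "CD", "EF")) - 1L,
                             design$pairs$p_better, design$pairs$p_worse,
                             par$alpha_G, par$alpha_L, par$beta)
      trials$chosen_better <- as.logical(sim$chose_better)
      trials$reward <- as.integer(sim$reward)
      trials$rt_ms <- if (is.null(rt)) NA_real_ else
        simulate_rt(nrow(trials), sched$day[i], group, rt)
      cbind(data.frame(day = sched$day[i], task_label = lab,
                       stringsAsFactors = FALSE), trials)
    })
    out <- do.call(rbind, sessions)
    # continuous trial numbering within each day (sessions run back to back)
    for (d in unique(out$day))
      out$trial_in_session[out$day == d] <- seq_len(sum(out$day == d))
    out
  })
}

#' Group-level parameter hierarchy used for simulation
#'
#' Subject-level parameters are drawn on transformed scales: learning
#' rates probit-normal, beta log-normal. Defaults put learning rates
#' around 0.31 (probit mean -0.5) and beta around 0.22 (log mean -1.5)
#' with modest individual variation, a regime typical for this task.
#'
#' @param mu_alphaG,mu_alphaL probit-scale group means of the learning
#'   rates.
#' @param mu_beta log-scale group mean of the exploration parameter.
#' @param sigma_alphaG,sigma_alphaL,sigma_beta group-level scales, > 0.
#' @return a `hyper_params` object.
#' @export
hyper_params <- function(mu_alphaG = -0.5, mu_alphaL = -0.5, mu_beta = -1.5,
                         sigma_alphaG = 0.25, sigma_alphaL = 0.25,
                         sigma_beta = 0.2) {
  if (any(c(sigma_alphaG, sigma_alphaL, sigma_beta) < 0))
    stop("group-level scales must be non-negative")
  structure(list(mu_alphaG = mu_alphaG, mu_alphaL = mu_alphaL,
                 mu_beta = mu_beta, sigma_alphaG = sigma_alphaG,
                 sigma_alphaL = sigma_alphaL, sigma_beta = sigma_beta),
            class = "hyper_params")
}

#' Day-2 shift effects on the transformed parameter scales
#'
#' `b` holds the common day-2 shift per parameter (what the natural
#' history group experiences: pure retest); `b_group` holds the extra
#' group-specific shift for the four manipulated groups. Defaults are the
#' posterior means estimated from the original cohort: on day 2 subjects
#' generally up-regulated learning from gains and down-regulated learning
#' from losses; the placebo arm additionally shifted toward loss-learning
#' with reduced noise and the nocebo arm toward gain-learning with
#' increased noise.
#'
#' @param b named numeric, common day effects for `alpha_G`, `alpha_L`,
#'   `beta` (transformed scales).
#' @param b_group 3 x 4 numeric matrix (rows `alpha_G`, `alpha_L`, `beta`;
#'   columns `placebo`, `nocebo`, `placebo_control`, `nocebo_control`).
#' @param sigma_b shrinkage scale of the effect prior (used when fitting,
#'   recorded here for completeness).
#' @return a `group_effects` object.
#' @export
group_effects <- function(b = c(alpha_G = 0.30, alpha_L = -0.22, beta = 0.03),
                          b_group = matrix(c(-0.20, 0.24, -0.16,
                                             0.22, -0.01, 0.28,
                                             0.25, -0.16, 0.19,
                                             0.16, 0.08, 0.03),
                                           nrow = 3,
                                           dimnames = list(
                                             RL_PARAMS,
                                             RL_GROUPS[-1])),
                          sigma_b = 1) {
  stopifnot(all(RL_PARAMS %in% names(b)),
            is.matrix(b_group), nrow(b_group) == 3L, ncol(b_group) == 4L,
            sigma_b > 0)
  structure(list(b = b[RL_PARAMS], b_group = b_group, sigma_b = sigma_b),
            class = "group_effects")
}

default_subjective_probs <- function() {
  # (decline, neutral, improve) per group and question; renormalized
  norm <- function(x) x / sum(x)
  list(
    expected = list(
      placebo         = norm(c(0.01, 0.29, 0.69)),
      nocebo          = norm(c(0.71, 0.22, 0.07)),
      placebo_control = norm(c(0.10, 0.40, 0.51)),
      nocebo_control  = norm(c(0.07, 0.61, 0.31))),
    perceived = list(
      placebo         = norm(c(0.02, 0.22, 0.75)),
      nocebo          = norm(c(0.81, 0.13, 0.06)),
      placebo_control = norm(c(0.32, 0.23, 0.45)),
      nocebo_control  = norm(c(0.14, 0.49, 0.37))))
}

#' Specification of a synthetic cohort
#'
#' @param n_per_group named integer vector of subjects per group; defaults
#'   to the study's five groups of 16.
#' @param hyper a [hyper_params()] object (generating truth).
#' @param effects a [group_effects()] object (generating truth).
#' @param subjective_probs nested list `question -> group -> length-3
#'   probability vector (decline, neutral, improve)` used to draw the
#'   subjective reports of the four manipulated groups; `NULL` disables.
#' @param rt an [rt_config()] or `NULL`.
#' @param designs optional named list of overriding `session_design`s.
#' @param single_alpha if `TRUE`, each subject's gain and loss learning
#'   rates are one and the same draw (generation from the
#'   single-learning-rate model).
#' @param share_days if `TRUE`, day-2 parameters equal day-1 parameters
#'   (no day redraw, no effects) as the single-alpha model assumes.
#' @param seed integer seed for cohort generation.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = stats::setNames(rep(16L, 5), RL_GROUPS),
                        hyper = hyper_params(), effects = group_effects(),
                        subjective_probs = default_subjective_probs(),
                        rt = rt_config(), designs = NULL,
                        single_alpha = FALSE, share_days = FALSE,
                        seed = 1L) {
  stopifnot(inherits(hyper, "hyper_params"), inherits(effects, "group_effects"))
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% RL_GROUPS))
    stop("n_per_group must be named with groups among: ",
         paste(RL_GROUPS, collapse = ", "))
  if (any(n_per_group < 1L)) stop("subject counts must be positive")
  structure(list(n_per_group = n_per_group, hyper = hyper, effects = effects,
                 subjective_probs = subjective_probs, rt = rt,
                 designs = designs, single_alpha = isTRUE(single_alpha),
                 share_days = isTRUE(share_days), seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_subject_params <- function(spec, group) {
  h <- spec$hyper
  e <- spec$effects
  mu <- c(alpha_G = h$mu_alphaG, alpha_L = h$mu_alphaL, beta = h$mu_beta)
  sg <- c(alpha_G = h$sigma_alphaG, alpha_L = h$sigma_alphaL,
          beta = h$sigma_beta)
  bg <- if (group == "NHG") c(alpha_G = 0, alpha_L = 0, beta = 0)
        else e$b_group[, group]
  t1 <- stats::rnorm(3, mu, sg)
  t2 <- if (spec$share_days) t1 else
    stats::rnorm(3, mu + e$b[RL_PARAMS] + bg, sg)
  names(t1) <- names(t2) <- RL_PARAMS
  if (spec$single_alpha) {
    t1["alpha_L"] <- t1["alpha_G"]
    t2["alpha_L"] <- t2["alpha_G"]
  }
  list(day1 = agent_params(to_natural(t1["alpha_G"]), to_natural(t1["alpha_L"]),
                           to_natural_beta(t1["beta"])),
       day2 = agent_params(to_natural(t2["alpha_G"]), to_natural(t2["alpha_L"]),
                           to_natural_beta(t2["beta"])),
       trans = rbind(day1 = t1, day2 = t2))
}

#' Simulate a full cohort under the two-day, five-group design
#'
#' Draws subject-level parameters from the generative hierarchy (probit
#' normal learning rates, log-normal beta, day-2 shifts on the transformed
#' scales), simulates every subject through their group's schedule, and
#' optionally draws categorical subjective reports for the manipulated
#' groups.
#'
#' @param spec a [cohort_spec()].
#' @return an `rl_cohort` list with elements `trials` (long-format trial
#'   table), `subjective` (one row per subject and question, or `NULL`),
#'   `true_params` (transformed-scale generating parameters per
#'   subject-day) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_preserved_seed(spec$seed, {
    trials <- list(); subj_rows <- list(); truth <- list()
    sid <- 0L
    for (group in names(spec$n_per_group)) {
      for (k in seq_len(spec$n_per_group[[group]])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)
        par <- draw_subject_params(spec, group)
        rec <- simulate_subject(par$day1, par$day2, group,
                                designs = spec$designs, rt = spec$rt)
        trials[[sid]] <- cbind(data.frame(subject_id = id, group = group,
                                          stringsAsFactors = FALSE), rec)
        truth[[sid]] <- data.frame(subject_id = id, group = group,
                                   day = c(1L, 2L),
                                   alpha_G = par$trans[, "alpha_G"],
                                   alpha_L = par$trans[, "alpha_L"],
                                   beta = par$trans[, "beta"],
                                   row.names = NULL)
        if (!is.null(spec$subjective_probs) && group != "NHG") {
          resp <- vapply(c("expected", "perceived"), function(q) {
            p <- spec$subjective_probs[[q]][[group]]
            sample(c("decline", "neutral", "improve"), 1L, prob = p)
          }, character(1))
          subj_rows[[length(subj_rows) + 1L]] <-
            data.frame(subject_id = id, group = group,
                       question = c("expected", "perceived"),
                       response = resp, stringsAsFactors = FALSE,
                       row.names = NULL)
        }
      }
    }
    structure(list(trials = do.call(rbind, trials),
                   subjective = if (length(subj_rows))
                     do.call(rbind, subj_rows) else NULL,
                   true_params = do.call(rbind, truth),
                   spec = spec),
              class = "rl_cohort")
  })
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat("Simulated cohort:", length(unique(x$trials$subject_id)), "subjects,",
      nrow(x$trials), "trials\n")
  print(table(group = x$trials$group, day = x$trials$day) /
          1L)
  invisible(x)
}
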