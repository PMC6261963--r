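# Hierarchical Bayesian regressions for accuracy, reaction time and the
# three-category subjective performance reports. Models are expressed in
# BUGS and sampled with JAGS (rjags); the module exposes the same
# diagnostic contract as the RL fits (split R-hat, warning on > 1.1).

BEHAVIOR_LEVELS <- c("base", "group", "group_day")

#' Build the model-ready trial table for the behavioral regressions
#'
#' Treatment-coded design with baselines pair AB, day 1 and group NHG;
#' the trial index is z-scored over the included rows. For the accuracy
#' outcome all answered trials are included; for reaction time, answered
#' trials with a recorded RT (no outlier trimming by default).
#'
#' @param trials long-format trial table.
#' @param outcome `"accuracy"` or `"rt"`.
#' @return data.frame with `subject_id`, `y`, `trial_z`, `pair`, `day01`,
#'   `group` (factors with the stated baselines).
#' @export
build_design <- function(trials, outcome = c("accuracy", "rt")) {
  outcome <- match.arg(outcome)
  if (inherits(trials, "rl_cohort")) trials <- trials$trials
  req <- c("subject_id", "group", "day", "trial_in_session", "pair_id",
           "chosen_better", if (outcome == "rt") "rt_ms")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials missing columns: ", paste(miss, collapse = ", "))
  keep <- !is.na(trials$chosen_better)
  if (outcome == "rt") keep <- keep & !is.na(trials$rt_ms)
  d <- trials[keep, , drop = FALSE]
  grp_lv <- c("NHG", setdiff(unique(d$group), "NHG"))
  out <- data.frame(
    subject_id = d$subject_id,
    y = if (outcome == "accuracy") as.integer(d$chosen_better) else d$rt_ms,
    trial_z = as.numeric(scale(d$trial_in_session)),
    pair = factor(d$pair_id, levels = c("AB", "CD", "EF")),
    day01 = as.integer(d$day == 2L),
    group = factor(d$group, levels = grp_lv),
    stringsAsFactors = FALSE)
  attr(out, "outcome") <- outcome
  out
}

behavior_formula <- function(level) {
  switch(level,
         base = ~ trial_z * pair + trial_z * day01,
         group = ~ trial_z * pair + trial_z * day01 + group,
         group_day = ~ trial_z * pair + trial_z * day01 + group +
           day01:group)
}

jags_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch)))
}

coda_to_array <- function(samp) {
  it <- nrow(samp[[1]])
  arr <- array(NA_real_, dim = c(it, length(samp), ncol(samp[[1]])),
               dimnames = list(NULL, NULL, colnames(samp[[1]])))
  for (ch in seq_along(samp)) arr[, ch, ] <- as.matrix(samp[[ch]])
  arr
}

logistic_bugs <- "
model {
  for (n in 1:N) {
    y[n] ~ dbern(p[n])
    logit(p[n]) <- inprod(X[n, ], b) + inprod(Zr[n, ], u[subj[n], ])
  }
  for (j in 1:P) { b[j] ~ dnorm(0, 0.04) }
  for (s in 1:S) { u[s, 1:R] ~ dmnorm(zero, Omega) }
  Omega ~ dwish(IR, Rp1)
}"

gaussian_bugs <- "
model {
  for (n in 1:N) {
    y[n] ~ dnorm(mu[n], tau)
    mu[n] <- inprod(X[n, ], b) + inprod(Zr[n, ], u[subj[n], ])
  }
  for (j in 1:P) { b[j] ~ dnorm(0, 1.0E-6) }
  for (s in 1:S) { u[s, 1:R] ~ dmnorm(zero, Omega) }
  Omega ~ dwish(IR, Rp1)
  tau <- pow(sigma_y, -2)
  sigma_y ~ dunif(0, 1000)
}"

#' Fit a hierarchical Bayesian accuracy or reaction-time regression
#'
#' Logistic regression (logit link) for accuracy, Gaussian with identity
#' link for reaction times in milliseconds. Fixed effects follow the
#' model ladder: the base model (trial, pair, day and the trial
#' interactions), `+ group`, and `+ group + day:group`. Subject-level
#' random effects (intercept, trial slope, pair offsets) are correlated
#' multivariate normal with a Wishart prior on the precision. Fixed
#' effects get weakly-informative normal priors (sd 5 on the logit scale,
#' essentially flat on the millisecond scale).
#'
#' @param design output of [build_design()].
#' @param level `"base"`, `"group"` or `"group_day"`.
#' @param chains,warmup,iter MCMC settings (JAGS adaptation plus burn-in
#'   equal to `warmup`).
#' @param seed integer seed (per-chain RNG streams derived from it).
#' @return a `behavior_fit`: coefficient draws, random-effect draws, the
#'   design matrices (for pointwise likelihoods), R-hat per fixed effect.
#' @export
fit_behavior <- function(design, level = c("group_day", "group", "base"),
                         chains = 3L, warmup = 500L, iter = 1000L,
                         seed = 1L) {
  level <- match.arg(level)
  outcome <- attr(design, "outcome")
  if (is.null(outcome)) stop("design must come from build_design()")
  X <- stats::model.matrix(behavior_formula(level), design)
  Zr <- stats::model.matrix(~ trial_z + pair, design)  # random-effect design
  subj <- match(design$subject_id, unique(design$subject_id))
  S <- max(subj); R <- ncol(Zr)
  dat <- list(y = design$y, X = X, Zr = Zr, subj = subj,
              N = nrow(X), P = ncol(X), S = S,
              zero = rep(0, R), IR = diag(R), Rp1 = R + 1)
  bugs <- if (outcome == "accuracy") logistic_bugs else gaussian_bugs
  bugs <- gsub("1:R", sprintf("1:%d", R), bugs)
  monitors <- c("b", "u", if (outcome == "rt") "sigma_y")
  jm <- rjags::jags.model(textConnection(bugs), data = dat,
                          n.chains = chains, n.adapt = warmup,
                          inits = jags_inits(chains, seed), quiet = TRUE)
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter)
  arr <- coda_to_array(samp)
  coef_names <- colnames(X)
  b_cols <- paste0("b[", seq_len(ncol(X)), "]")
  dimnames(arr)[[3]][match(b_cols, dimnames(arr)[[3]])] <- coef_names
  rh <- rhat(arr[, , coef_names, drop = FALSE])
  if (max(rh, na.rm = TRUE) > 1.1)
    warning(sprintf("behavior regression not converged: max R-hat = %.3f",
                    max(rh, na.rm = TRUE)))
  structure(list(outcome = outcome, level = level, draws = arr,
                 coef_names = coef_names, X = X, Zr = Zr, subj = subj,
                 y = design$y, rhat = rh, seed = seed),
            class = "behavior_fit")
}

#' @export
print.behavior_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s regression (%s model): %d fixed effects\n",
              x$outcome, x$level, length(x$coef_names)))
  m <- behavior_coef_matrix(x)
  for (nm in x$coef_names) {
    h <- hdi(m[, nm])
    cat(sprintf("  %-28s %8.2f [%.2f, %.2f]\n", nm, mean(m[, nm]), h[1], h[2]))
  }
  invisible(x)
}

behavior_coef_matrix <- function(fit) {
  arr <- fit$draws[, , fit$coef_names, drop = FALSE]
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  colnames(m) <- fit$coef_names
  m
}

#' Posterior summary table of a behavioral regression
#'
#' @param fit a `behavior_fit`.
#' @param mass HDI mass.
#' @return data.frame `term`, `mean`, `lower`, `upper` (Table-style
#'   layout: one row per fixed effect).
#' @export
behavior_summary <- function(fit, mass = 0.95) {
  m <- behavior_coef_matrix(fit)
  out <- do.call(rbind, lapply(colnames(m), function(nm) {
    h <- hdi(m[, nm], mass)
    data.frame(term = nm, mean = mean(m[, nm]), lower = h[1], upper = h[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pointwise log-likelihood matrix of a behavioral regression
#'
#' @param fit a `behavior_fit`.
#' @param max_draws maximum posterior draws to evaluate.
#' @return matrix `draws x observations`, for use with [psis_loo()].
#' @export
behavior_pointwise <- function(fit, max_draws = 500L) {
  arr <- fit$draws
  d <- dim(arr)
  keep <- unique(round(seq(1, d[1], length.out =
                             min(d[1], ceiling(max_draws / d[2])))))
  S <- max(fit$subj); R <- ncol(fit$Zr)
  u_names <- as.vector(outer(seq_len(S), seq_len(R),
                             function(s, r) sprintf("u[%d,%d]", s, r)))
  out <- matrix(NA_real_, length(keep) * d[2], length(fit$y))
  row <- 0L
  for (ch in seq_len(d[2])) {
    for (it in keep) {
      row <- row + 1L
      b <- arr[it, ch, fit$coef_names]
      U <- matrix(arr[it, ch, u_names], S, R)
      eta <- drop(fit$X %*% b) + rowSums(fit$Zr * U[fit$subj, , drop = FALSE])
      out[row, ] <- if (fit$outcome == "accuracy") {
        ifelse(fit$y == 1L, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))
      } else {
        stats::dnorm(fit$y, eta, arr[it, ch, "sigma_y"], log = TRUE)
      }
    }
  }
  out
}

#' Posterior contrast between two day-by-group interaction coefficients
#'
#' The per-draw difference of the `day:group` coefficients of two groups
#' (`"NHG"` counts as zero, being the baseline), summarizing how much
#' more one group improved from day 1 to day 2 than the other.
#'
#' @param fit a `behavior_fit` of the `group_day` model.
#' @param groupA,groupB group labels.
#' @param mass HDI mass.
#' @return a `behavior_contrast`: draws of delta plus mean and HDI.
#' @export
contrast <- function(fit, groupA, groupB, mass = 0.95) {
  stopifnot(inherits(fit, "behavior_fit"))
  if (fit$level != "group_day")
    stop("contrasts need the model with the day:group interaction")
  m <- behavior_coef_matrix(fit)
  coef_of <- function(g) {
    if (g == "NHG") return(rep(0, nrow(m)))
    nm <- paste0("day01:group", g)
    if (!nm %in% colnames(m))
      stop("no day:group coefficient for group ", g)
    m[, nm]
  }
  delta <- coef_of(groupA) - coef_of(groupB)
  h <- hdi(delta, mass)
  structure(list(groupA = groupA, groupB = groupB, draws = delta,
                 mean = mean(delta), lower = h[1], upper = h[2]),
            class = "behavior_contrast")
}

#' @export
print.behavior_contrast <- function(x, ...) {
  cat(sprintf("delta(%s - %s) = %.2f [%.2f, %.2f]\n", x$groupA, x$groupB,
              x$mean, x$lower, x$upper))
  invisible(x)
}

subjective_design_row <- function(group, question) {
  data.frame(
    manipulation = factor(
      if (group %in% c("placebo", "placebo_control")) "placebo" else "nocebo",
      levels = c("placebo", "nocebo")),
    question = factor(question, levels = c("expected", "perceived")),
    grouptype = factor(
      if (group %in% c("placebo", "nocebo")) "experimental" else "control",
      levels = c("control", "experimental")))
}

subjective_formula <- ~ manipulation + question + grouptype +
  grouptype:question + grouptype:manipulation

softmax_bugs <- "
model {
  for (n in 1:N) {
    y[n] ~ dcat(p[n, 1:3])
    for (k in 1:3) { p[n, k] <- e[n, k] / sum(e[n, 1:3]) }
    e[n, 1] <- exp(inprod(X[n, ], b_decline))
    e[n, 2] <- 1
    e[n, 3] <- exp(inprod(X[n, ], b_improve))
  }
  for (j in 1:P) {
    b_decline[j] ~ dnorm(0, 0.16)
    b_improve[j] ~ dnorm(0, 0.16)
  }
}"

#' Fit the three-category softmax regression for subjective reports
#'
#' Multinomial-logit model of the decline/neutral/improve responses of
#' the four manipulated groups, with factors task-manipulation (placebo
#' vs nocebo arm), question (expected vs perceived) and group (control vs
#' experimental) plus the group-by-question and group-by-manipulation
#' interactions. "neutral" is the fixed reference category; coefficients
#' get Normal(0, 2.5) priors, which also regularize empty cells. Derived
#' response probabilities (the reported quantity) are invariant to the
#' reference choice.
#'
#' @param responses data.frame with `subject_id`, `group`, `question`
#'   (`"expected"`/`"perceived"`), `response`
#'   (`"decline"`/`"neutral"`/`"improve"`); one response per subject and
#'   question.
#' @param chains,warmup,iter,seed MCMC settings.
#' @return a `subjective_fit` with coefficient draws for the decline and
#'   improve categories.
#' @export
fit_subjective <- function(responses, chains = 3L, warmup = 500L,
                           iter = 1000L, seed = 1L) {
  req <- c("subject_id", "group", "question", "response")
  miss <- setdiff(req, names(responses))
  if (length(miss)) stop("responses missing columns: ",
                         paste(miss, collapse = ", "))
  dup <- duplicated(responses[, c("subject_id", "question")])
  if (any(dup)) stop("each subject must contribute one response per question")
  cats <- c("decline", "neutral", "improve")
  if (!all(responses$response %in% cats))
    stop("responses must be one of: ", paste(cats, collapse = ", "))
  fac <- do.call(rbind, lapply(seq_len(nrow(responses)), function(i)
    subjective_design_row(responses$group[i], responses$question[i])))
  X <- stats::model.matrix(subjective_formula, fac)
  dat <- list(y = match(responses$response, cats), X = X,
              N = nrow(X), P = ncol(X))
  jm <- rjags::jags.model(textConnection(softmax_bugs), data = dat,
                          n.chains = chains, n.adapt = warmup,
                          inits = jags_inits(chains, seed), quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("b_decline", "b_improve"), n.iter = iter)
  arr <- coda_to_array(samp)
  nm <- dimnames(arr)[[3]]
  nm <- sub("^b_decline\\[(\\d+)\\]$", "decline_\\1", nm)
  nm <- sub("^b_improve\\[(\\d+)\\]$", "improve_\\1", nm)
  dimnames(arr)[[3]] <- nm
  rh <- rhat(arr)
  if (max(rh, na.rm = TRUE) > 1.1)
    warning(sprintf("subjective regression not converged: max R-hat = %.3f",
                    max(rh, na.rm = TRUE)))
  structure(list(draws = arr, coef_names = colnames(X), rhat = rh,
                 seed = seed),
            class = "subjective_fit")
}

#' Implied response probabilities for one group and question
#'
#' For every posterior draw, the linear predictors of the three response
#' categories in the requested cell are pushed through the softmax,
#' giving a probability triple that sums to one exactly; the triples are
#' summarized by posterior means and HDIs.
#'
#' @param fit a `subjective_fit`.
#' @param group one of the four manipulated groups.
#' @param question `"expected"` or `"perceived"`.
#' @param mass HDI mass.
#' @return a `response_probabilities` data.frame: one row per category
#'   with `mean`, `lower`, `upper`; the per-draw triples are attached as
#'   attribute `"draws"`.
#' @export
implied_probabilities <- function(fit, group, question, mass = 0.95) {
  stopifnot(inherits(fit, "subjective_fit"))
  group <- match.arg(group, RL_GROUPS[-1])
  question <- match.arg(question, c("expected", "perceived"))
  x <- stats::model.matrix(subjective_formula,
                           subjective_design_row(group, question))
  d <- dim(fit$draws)
  P <- length(fit$coef_names)
  flat <- matrix(fit$draws, d[1] * d[2], d[3])
  colnames(flat) <- dimnames(fit$draws)[[3]]
  eta_dec <- drop(flat[, paste0("decline_", seq_len(P))] %*% t(x))
  eta_imp <- drop(flat[, paste0("improve_", seq_len(P))] %*% t(x))
  e <- cbind(decline = exp(eta_dec), neutral = 1, improve = exp(eta_imp))
  p <- e / rowSums(e)
  out <- do.call(rbind, lapply(colnames(p), function(k) {
    h <- hdi(p[, k], mass)
    data.frame(group = group, question = question, response = k,
               mean = mean(p[, k]), lower = h[1], upper = h[2],
               stringsAsFactors = FALSE)
  }))
  attr(out, "draws") <- p
  class(out) <- c("response_probabilities", "data.frame")
  out
}
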