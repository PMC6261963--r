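#' Prior configuration for the hierarchical RL model
#'
#' Defaults are the weakly-informative priors of the original analysis:
#' probit-scale learning-rate means Normal(-0.5, 0.6), log-scale beta mean
#' Normal(-1.5, 0.8), sigma_alpha half-Cauchy(0.01), sigma_beta
#' half-Normal(0.3) and a half-Normal(1) on the shrinkage scale of the
#' day/group effects (the scale prior is stated as Normal(0, 1); being a
#' scale it is implemented on positive support). The implied priors put
#' most learning-rate mass below 0.5 and most beta mass well below 2.
#'
#' @param mu_alpha,mu_beta length-2 `c(location, scale)` of the normal
#'   priors on the group-level means (probit / log scale).
#' @param sigma_alpha,sigma_beta `list(dist, scale)` with `dist` one of
#'   `"half_cauchy"`, `"half_normal"`.
#' @param sigma_b prior on the effect-shrinkage scale, same form.
#' @return a `prior_config` object.
#' @export
prior_config <- function(mu_alpha = c(-0.5, 0.6),
                         mu_beta = c(-1.5, 0.8),
                         sigma_alpha = list(dist = "half_cauchy", scale = 0.01),
                         sigma_beta = list(dist = "half_normal", scale = 0.3),
                         sigma_b = list(dist = "half_normal", scale = 1)) {
  chk <- function(p) {
    stopifnot(p$dist %in% c("half_cauchy", "half_normal"), p$scale > 0)
    p
  }
  stopifnot(length(mu_alpha) == 2L, mu_alpha[2] > 0,
            length(mu_beta) == 2L, mu_beta[2] > 0)
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta,
                 sigma_alpha = chk(sigma_alpha), sigma_beta = chk(sigma_beta),
                 sigma_b = chk(sigma_b)),
            class = "prior_config")
}

# log-density (including log|Jacobian| of the log transform) and gradient
# w.r.t. log(sigma) of the positive-scale priors
scale_prior_lp <- function(log_sig, prior) {
  sig <- exp(log_sig)
  s <- prior$scale
  if (prior$dist == "half_normal") {
    list(lp = -sig^2 / (2 * s^2) + log_sig,
         grad = -sig^2 / s^2 + 1)
  } else { # half_cauchy
    list(lp = -log1p((sig / s)^2) + log_sig,
         grad = -2 * sig^2 / (s^2 + sig^2) + 1)
  }
}

# Flatten a cohort's trial table into the arrays the C++ likelihood needs.
# Missed trials are dropped (no feedback was delivered, Q does not advance).
rl_data <- function(trials) {
  req <- c("subject_id", "group", "day", "task_label", "pair_id",
           "chosen_better", "reward")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials missing columns: ", paste(miss, collapse = ", "))
  trials <- trials[!is.na(trials$chosen_better), , drop = FALSE]
  subj <- unique(trials$subject_id)
  grp_of <- vapply(subj, function(s)
    trials$group[match(s, trials$subject_id)], character(1))
  ord <- order(match(trials$subject_id, subj), trials$day,
               seq_len(nrow(trials)))
  trials <- trials[ord, , drop = FALSE]
  key <- paste(trials$subject_id, trials$day, trials$task_label, sep = "\r")
  segs <- rle(key)
  seg_len <- segs$lengths
  seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
  first <- seg_start + 1L
  list(pair = pair_index0(trials$pair_id),
       chosen = as.integer(trials$chosen_better),
       reward = as.integer(trials$reward),
       seg_start = as.integer(seg_start),
       seg_len = as.integer(seg_len),
       seg_subj = match(trials$subject_id[first], subj),
       seg_day = as.integer(trials$day[first]),
       subjects = subj, groups = grp_of, n_trials = nrow(trials),
       trials = trials)
}

#' Build a hierarchical Bayesian RL model for a cohort
#'
#' Three nested variants form the model ladder:
#' \describe{
#'   \item{M1_single_alpha}{one learning rate and one beta per subject,
#'     shared across days; no day or group effects.}
#'   \item{M2_day_group}{single learning rate, but parameters redrawn on
#'     day 2 around means shifted by a common day effect plus a
#'     group-specific effect.}
#'   \item{M3_full}{separate gain/loss learning rates, all three
#'     parameters varying by day and group (the full model).}
#' }
#' Subject-level parameters are non-centered: `theta = loc + sigma * z`
#' with `z ~ Normal(0, 1)`, a posterior-equivalent reparameterization
#' that samples efficiently. The group-specific effects share a
#' `Normal(0, sigma_b)` shrinkage prior (12 effects in the full
#' five-group design); the common day effects get a fixed
#' weakly-informative `Normal(0, 1)` prior by default. Pooling the day
#' effects into the shrinkage distribution as well (15 shrunken effects,
#' `shrink_day_effects = TRUE`) lets a handful of small group effects
#' pull the shared scale down and over-shrink genuinely large day
#' effects, so the unpooled form is the default.
#'
#' @param trials long-format trial table (see [simulate_cohort()] or
#'   [read_trials()]).
#' @param variant `"M3_full"`, `"M2_day_group"` or `"M1_single_alpha"`.
#' @param priors a [prior_config()].
#' @param shrink_day_effects if `TRUE`, the common day effects join the
#'   `Normal(0, sigma_b)` shrinkage pool instead of the fixed
#'   Normal(0, 1) prior.
#' @return an `rl_model` object with the flattened data, the parameter
#'   index map, and `$logp_grad(q)` returning the joint log-density and
#'   its gradient on the unconstrained scale.
#' @export
build_model <- function(trials,
                        variant = c("M3_full", "M2_day_group",
                                    "M1_single_alpha"),
                        priors = prior_config(),
                        shrink_day_effects = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "prior_config"))
  if (inherits(trials, "rl_cohort")) trials <- trials$trials
  dat <- rl_data(trials)
  S <- length(dat$subjects)
  K <- if (variant == "M3_full") 3L else 2L
  par_names_k <- if (K == 3L) c("alphaG", "alphaL", "beta")
                 else c("alpha", "beta")
  has_effects <- variant != "M1_single_alpha"
  grp_levels <- setdiff(unique(dat$groups), "NHG")

  # parameter sets: per subject (M1) or per subject-day (M2/M3)
  if (has_effects) {
    D <- 2L * S
    set_of_seg <- 2L * (dat$seg_subj - 1L) + dat$seg_day
    day2 <- rep(c(FALSE, TRUE), times = S)
    set_grp <- rep(match(dat$groups, grp_levels, nomatch = 0L), each = 2L)
  } else {
    D <- S
    set_of_seg <- dat$seg_subj
    day2 <- rep(FALSE, S)
    set_grp <- rep(0L, S)
  }

  nm <- character(0)
  idx <- list()
  add <- function(names) {
    out <- length(nm) + seq_along(names)
    nm <<- c(nm, names)
    out
  }
  idx$mu <- add(paste0("mu_", par_names_k))
  idx$log_sigma <- add(paste0("log_sigma_", par_names_k))
  if (has_effects) {
    idx$b_day <- add(paste0("b_", par_names_k))
    if (length(grp_levels))
      idx$b_group <- matrix(
        add(as.vector(outer(par_names_k, grp_levels,
                            function(p, g) paste0("b_", p, "_", g)))),
        nrow = K)
    idx$log_sigma_b <- add("log_sigma_b")
  }
  zn <- as.vector(outer(seq_len(D), par_names_k, function(d, p)
    paste0("z_", p, "[", d, "]")))
  idx$z <- matrix(add(zn), nrow = D)

  n_par <- length(nm)
  alpha_rows <- seq_len(K - 1L)   # rows of trans holding learning rates
  beta_row <- K

  logp_grad <- function(q) {
    mu <- q[idx$mu]
    log_sigma <- q[idx$log_sigma]
    sigma <- exp(log_sigma)
    Z <- matrix(q[idx$z], D, K)
    loc <- matrix(mu, D, K, byrow = TRUE)
    if (has_effects) {
      b <- q[idx$b_day]
      loc <- loc + outer(day2, b)
      if (length(grp_levels)) {
        Bg <- matrix(q[idx$b_group], K, length(grp_levels))
        on2 <- which(day2 & set_grp > 0L)
        if (length(on2))
          loc[on2, ] <- loc[on2, ] + t(Bg[, set_grp[on2], drop = FALSE])
      }
    }
    trans <- loc + Z %*% diag(sigma, K)

    if (K == 3L) {
      aG <- stats::pnorm(trans[, 1]); aL <- stats::pnorm(trans[, 2])
      be <- exp(trans[, 3])
    } else {
      aG <- aL <- stats::pnorm(trans[, 1]); be <- exp(trans[, 2])
    }
    res <- rl_loglik_grad_cpp(dat$pair, dat$chosen, dat$reward,
                              dat$seg_start, dat$seg_len, set_of_seg - 1L,
                              aG, aL, be)
    lp <- res$loglik
    gN <- res$grad
    dtrans <- matrix(0, D, K)
    if (K == 3L) {
      dtrans[, 1] <- gN[, 1] * stats::dnorm(trans[, 1])
      dtrans[, 2] <- gN[, 2] * stats::dnorm(trans[, 2])
      dtrans[, 3] <- gN[, 3] * be
    } else {
      dtrans[, 1] <- (gN[, 1] + gN[, 2]) * stats::dnorm(trans[, 1])
      dtrans[, 2] <- gN[, 3] * be
    }

    g <- numeric(n_par)
    # z: likelihood chain rule + standard-normal prior
    g[idx$z] <- as.vector(dtrans %*% diag(sigma, K)) - q[idx$z]
    lp <- lp - 0.5 * sum(Z^2)
    g[idx$mu] <- colSums(dtrans)
    g[idx$log_sigma] <- colSums(dtrans * Z) * sigma
    if (has_effects) {
      g[idx$b_day] <- colSums(dtrans[day2, , drop = FALSE])
      if (length(grp_levels)) {
        for (gi in seq_along(grp_levels)) {
          sel <- day2 & set_grp == gi
          g[idx$b_group[, gi]] <- colSums(dtrans[sel, , drop = FALSE])
        }
      }
    }

    # priors on group-level means
    for (k in alpha_rows) {
      lp <- lp - (mu[k] - priors$mu_alpha[1])^2 / (2 * priors$mu_alpha[2]^2)
      g[idx$mu[k]] <- g[idx$mu[k]] -
        (mu[k] - priors$mu_alpha[1]) / priors$mu_alpha[2]^2
    }
    lp <- lp - (mu[beta_row] - priors$mu_beta[1])^2 / (2 * priors$mu_beta[2]^2)
    g[idx$mu[beta_row]] <- g[idx$mu[beta_row]] -
      (mu[beta_row] - priors$mu_beta[1]) / priors$mu_beta[2]^2

    # priors on group-level scales (with log-transform Jacobian)
    for (k in seq_len(K)) {
      pr <- if (k %in% alpha_rows) priors$sigma_alpha else priors$sigma_beta
      sp <- scale_prior_lp(log_sigma[k], pr)
      lp <- lp + sp$lp
      g[idx$log_sigma[k]] <- g[idx$log_sigma[k]] + sp$grad
    }

    if (has_effects) {
      log_sigma_b <- q[idx$log_sigma_b]
      sigma_b <- exp(log_sigma_b)
      eff <- if (length(grp_levels)) c(b, q[idx$b_group]) else b
      eff_idx <- if (length(grp_levels)) c(idx$b_day, as.vector(idx$b_group))
                 else idx$b_day
      if (shrink_day_effects) {
        shr <- eff; shr_idx <- eff_idx
      } else {
        shr <- if (length(grp_levels)) q[idx$b_group] else numeric(0)
        shr_idx <- if (length(grp_levels)) as.vector(idx$b_group) else integer(0)
        lp <- lp - 0.5 * sum(b^2)
        g[idx$b_day] <- g[idx$b_day] - b
      }
      if (length(shr)) {
        lp <- lp - sum(shr^2) / (2 * sigma_b^2) - length(shr) * log_sigma_b
        g[shr_idx] <- g[shr_idx] - q[shr_idx] / sigma_b^2
        g[idx$log_sigma_b] <- g[idx$log_sigma_b] +
          sum(shr^2) / sigma_b^2 - length(shr)
      }
      sp <- scale_prior_lp(log_sigma_b, priors$sigma_b)
      lp <- lp + sp$lp
      g[idx$log_sigma_b] <- g[idx$log_sigma_b] + sp$grad
    }
    list(lp = lp, grad = g)
  }

  # natural-scale subject-day parameters for a matrix of draws
  natural_params <- function(draws) {
    # draws: matrix n_draws x n_par (unconstrained)
    nd <- nrow(draws)
    sigma <- exp(draws[, idx$log_sigma, drop = FALSE])
    out <- vector("list", K)
    trans_all <- array(0, dim = c(nd, D, K))
    for (k in seq_len(K)) {
      loc <- matrix(draws[, idx$mu[k]], nd, D)
      if (has_effects) {
        loc <- loc + outer(draws[, idx$b_day[k]], as.numeric(day2))
        if (length(grp_levels)) {
          for (gi in seq_along(grp_levels)) {
            sel <- which(day2 & set_grp == gi)
            if (length(sel))
              loc[, sel] <- loc[, sel] + draws[, idx$b_group[k, gi]]
          }
        }
      }
      trans_all[, , k] <- loc +
        draws[, idx$z[, k], drop = FALSE] * sigma[, k]
    }
    take <- function(k) matrix(trans_all[, , k], nrow = nd)
    if (K == 3L) {
      list(alpha_G = stats::pnorm(take(1)), alpha_L = stats::pnorm(take(2)),
           beta = exp(take(3)))
    } else {
      a <- stats::pnorm(take(1))
      list(alpha_G = a, alpha_L = a, beta = exp(take(2)))
    }
  }

  init <- function() {
    q0 <- numeric(n_par)
    q0[idx$mu] <- c(rep(priors$mu_alpha[1], K - 1L), priors$mu_beta[1]) +
      stats::rnorm(K, 0, 0.1)
    q0[idx$log_sigma] <- log(0.2) + stats::rnorm(K, 0, 0.1)
    if (has_effects) {
      q0[idx$b_day] <- stats::rnorm(K, 0, 0.05)
      if (length(grp_levels))
        q0[idx$b_group] <- stats::rnorm(length(idx$b_group), 0, 0.05)
      q0[idx$log_sigma_b] <- log(0.5) + stats::rnorm(1, 0, 0.1)
    }
    q0[idx$z] <- stats::rnorm(length(idx$z), 0, 0.1)
    q0
  }

  structure(list(variant = variant, priors = priors,
                 shrink_day_effects = shrink_day_effects,
                 data = dat, n_params = n_par, param_names = nm,
                 idx = idx, K = K, D = D, day2 = day2, set_grp = set_grp,
                 set_of_seg = set_of_seg, grp_levels = grp_levels,
                 logp_grad = logp_grad, natural_params = natural_params,
                 init = init),
            class = "rl_model")
}

#' @export
print.rl_model <- function(x, ...) {
  cat("Hierarchical RL model", x$variant, "\n")
  cat(sprintf("  %d subjects, %d trials, %d free parameters\n",
              length(x$data$subjects), x$data$n_trials, x$n_params))
  invisible(x)
}
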