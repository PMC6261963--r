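log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Pointwise log-likelihood matrix of a fitted RL model
#'
#' Entry (s, i) is the log-likelihood of trial i under the subject-level
#' parameters implied by posterior draw s. Draws are thinned evenly (per
#' chain) to at most `max_draws` to keep the matrix tractable.
#'
#' @param fit an `rl_fit`.
#' @param max_draws maximum number of posterior draws to evaluate.
#' @return matrix `draws x trials`.
#' @export
pointwise_matrix <- function(fit, max_draws = 1000L) {
  stopifnot(inherits(fit, "rl_fit"))
  model <- fit$model
  d <- dim(fit$draws)
  keep <- unique(round(seq(1, d[1], length.out =
                             min(d[1], ceiling(max_draws / d[2])))))
  sub <- fit$draws[keep, , , drop = FALSE]
  m <- matrix(sub, length(keep) * d[2], d[3])
  colnames(m) <- dimnames(fit$draws)[[3]]
  nat <- model$natural_params(m)
  S <- nrow(m)
  dat <- model$data
  out <- matrix(NA_real_, S, dat$n_trials)
  for (s in seq_len(S)) {
    res <- rl_loglik_grad_cpp(dat$pair, dat$chosen, dat$reward,
                              dat$seg_start, dat$seg_len,
                              model$set_of_seg - 1L,
                              nat$alpha_G[s, ], nat$alpha_L[s, ],
                              nat$beta[s, ])
    out[s, ] <- res$pointwise
  }
  out
}

# Generalized Pareto shape fit (Zhang & Stephens 2009 profile-posterior
# estimator) to sample exceedances x > 0, with the small-sample shape
# regularization customary for PSIS.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  q25 <- x[max(1L, floor(n / 4 + 0.5))]
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q25)
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(L - L[j])), numeric(1))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  sigma <- k / b
  k_reg <- k * n / (n + 10) + 5 / (2 * (n + 10))
  list(k = k_reg, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Smooth one column of log importance weights; returns the smoothed
# (max-centered, truncated-at-zero) weights and the Pareto-k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- Inf
  if (M >= 5L && stats::sd(lw) > 0) {
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1L):S]
    cut <- exp(lw[ord[S - M]])
    x <- exp(lw[tail_ids]) - cut
    if (sum(x > 0) >= 5L) {
      fit <- gpd_fit(x[x > 0])
      k <- fit$k
      if (is.finite(fit$k) && fit$sigma > 0) {
        p <- (seq_len(M) - 0.5) / M
        smoothed <- log(cut + gpd_quantile(p, fit$k, fit$sigma))
        lw[tail_ids[order(lw[tail_ids])]] <- smoothed
      }
    }
  }
  lw <- pmin(lw, 0)
  list(lw = lw, k = k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes elpd_loo and LOOIC = -2 elpd_loo from a pointwise
#' log-likelihood matrix. For each observation the raw importance weights
#' exp(-loglik) are stabilized by replacing the largest weights with
#' quantiles of a generalized Pareto distribution fitted to the weight
#' tail; the fitted shape k is reported per observation and values above
#' 0.7 trigger a warning (the estimate is kept, not silently dropped).
#' With very few draws (tail < 5) smoothing is skipped and the estimate
#' reduces to plain importance sampling.
#'
#' @param log_lik matrix `draws x observations`.
#' @param warn warn about high Pareto-k values (default `TRUE`).
#' @return a `psis_loo` object: `elpd_loo`, `se`, `looic`, `p_loo`
#'   (effective parameter count), pointwise `elpd_i` and `pareto_k`.
#' @export
psis_loo <- function(log_lik, warn = TRUE) {
  stopifnot(is.matrix(log_lik), all(is.finite(log_lik)))
  S <- nrow(log_lik); N <- ncol(log_lik)
  elpd_i <- numeric(N); k_i <- numeric(N); lpd_i <- numeric(N)
  for (i in seq_len(N)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)
    elpd_i[i] <- log_sum_exp(sm$lw + ll) - log_sum_exp(sm$lw)
    lpd_i[i] <- log_sum_exp(ll) - log(S)
    k_i[i] <- sm$k
  }
  n_bad <- sum(is.finite(k_i) & k_i > 0.7)
  if (warn && n_bad > 0)
    warning(n_bad, " observation(s) with Pareto k > 0.7; ",
            "elpd_loo may be unstable")
  elpd <- sum(elpd_i)
  structure(list(elpd_loo = elpd, se = sqrt(N * stats::var(elpd_i)),
                 looic = -2 * elpd, p_loo = sum(lpd_i) - elpd,
                 elpd_i = elpd_i, pareto_k = k_i,
                 n_draws = S, n_obs = N),
            class = "psis_loo")
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd_loo = %.2f (SE %.2f), LOOIC = %.2f, p_loo = %.1f\n",
              x$elpd_loo, x$se, x$looic, x$p_loo))
  cat(sprintf("  %d draws, %d observations, %d Pareto k > 0.7\n",
              x$n_draws, x$n_obs, sum(is.finite(x$pareto_k) &
                                        x$pareto_k > 0.7)))
  invisible(x)
}

#' Compare models by LOOIC
#'
#' Ranks models by elpd_loo and reports LOOIC differences relative to the
#' best model; absolute differences larger than the threshold (default
#' 10) are flagged as strong evidence.
#'
#' @param ... named `psis_loo` objects (all computed on the same
#'   observation set).
#' @param strong_threshold LOOIC difference considered strong.
#' @return a `loo_comparison` data.frame: `model`, `elpd_loo`, `looic`,
#'   `delta_looic`, `se_diff`, `strong`.
#' @export
compare_loo <- function(..., strong_threshold = 10) {
  loos <- list(...)
  if (length(loos) == 1L && is.list(loos[[1]]) &&
      !inherits(loos[[1]], "psis_loo")) loos <- loos[[1]]
  if (is.null(names(loos)) || any(names(loos) == ""))
    names(loos) <- paste0("model", seq_along(loos))
  stopifnot(all(vapply(loos, inherits, logical(1), "psis_loo")))
  n_obs <- vapply(loos, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L)
    stop("models were evaluated on differing observation sets: ",
         paste(n_obs, collapse = ", "))
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpd)
  se_diff <- vapply(seq_along(loos), function(i) {
    d <- loos[[i]]$elpd_i - loos[[best]]$elpd_i
    sqrt(length(d) * stats::var(d))
  }, numeric(1))
  out <- data.frame(model = names(loos),
                    elpd_loo = elpd,
                    looic = -2 * elpd,
                    delta_looic = -2 * (elpd - elpd[best]),
                    se_diff = se_diff,
                    stringsAsFactors = FALSE)
  out$strong <- abs(out$delta_looic) > strong_threshold
  out <- out[order(out$delta_looic), ]
  rownames(out) <- NULL
  class(out) <- c("loo_comparison", "data.frame")
  out
}
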