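# Hamiltonian Monte Carlo for the hierarchical RL posterior.
#
# Plain HMC with a jittered number of leapfrog steps, dual-averaging
# step-size adaptation targeting a given acceptance rate, and a diagonal
# metric estimated once mid-warmup from the accumulated draws. The
# gradient of the joint log-density is analytic (see build_model), so a
# transition costs one likelihood sweep per leapfrog step.

#' Sampler configuration
#'
#' Defaults follow the original fitting procedure: eight parallel chains,
#' 1000 warm-up iterations each, and 1000 retained draws per chain (8000
#' draws in total). Scaled-down studies pass smaller values.
#'
#' @param chains number of chains (run sequentially).
#' @param warmup warm-up (adaptation) iterations per chain, discarded.
#' @param iter retained post-warm-up iterations per chain.
#' @param max_leapfrog leapfrog steps are drawn uniformly from
#'   `1:max_leapfrog` each transition.
#' @param target_accept dual-averaging acceptance target.
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(chains = 8L, warmup = 1000L, iter = 1000L,
                           max_leapfrog = 24L, target_accept = 0.8) {
  stopifnot(chains >= 1L, warmup >= 50L, iter >= 1L, max_leapfrog >= 1L,
            target_accept > 0, target_accept < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter),
                 max_leapfrog = as.integer(max_leapfrog),
                 target_accept = target_accept),
            class = "sampler_config")
}

find_reasonable_eps <- function(lpg, q0) {
  eps <- 0.1
  st <- lpg(q0)
  p0 <- stats::rnorm(length(q0))
  H0 <- -st$lp + 0.5 * sum(p0^2)
  one_step <- function(eps) {
    p <- p0 + 0.5 * eps * st$grad
    q <- q0 + eps * p
    s1 <- lpg(q)
    if (!is.finite(s1$lp)) return(Inf)
    p <- p + 0.5 * eps * s1$grad
    (-s1$lp + 0.5 * sum(p^2)) - H0
  }
  dH <- one_step(eps)
  dir <- if (is.finite(dH) && exp(-dH) > 0.5) 1 else -1
  for (i in 1:30) {
    eps <- eps * 2^dir
    dH <- one_step(eps)
    ok <- is.finite(dH) && exp(-dH) > 0.5
    if ((dir == 1 && !ok) || (dir == -1 && ok)) break
  }
  max(eps, 1e-8)
}

run_hmc_chain <- function(lpg, q0, warmup, iter, max_leapfrog, target_accept,
                          progress_tag = NULL) {
  n <- length(q0)
  minv <- rep(1, n)             # diagonal estimate of posterior variances
  eps <- find_reasonable_eps(lpg, q0)
  mu_da <- log(10 * eps)
  log_eps_bar <- 0; Hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_iter <- 0L

  q <- q0
  st <- lpg(q)
  total <- warmup + iter
  draws <- matrix(NA_real_, iter, n)
  warm_keep <- matrix(NA_real_, 0, n)
  w_lo <- floor(0.25 * warmup); w_hi <- floor(0.75 * warmup)
  warm_buf <- matrix(NA_real_, w_hi - w_lo, n)
  n_div <- 0L; acc_sum <- 0

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(n) / sqrt(minv)
    L <- sample.int(max_leapfrog, 1L)
    p <- p0 + 0.5 * eps * st$grad
    qn <- q + eps * (minv * p)
    sn <- lpg(qn)
    ok <- is.finite(sn$lp)
    if (ok && L > 1L) {
      for (l in seq_len(L - 1L)) {
        p <- p + eps * sn$grad
        qn <- qn + eps * (minv * p)
        sn <- lpg(qn)
        if (!is.finite(sn$lp)) { ok <- FALSE; break }
      }
    }
    if (ok) p <- p + 0.5 * eps * sn$grad
    H0 <- -st$lp + 0.5 * sum(p0^2 * minv)
    H1 <- if (ok) -sn$lp + 0.5 * sum(p^2 * minv) else Inf
    dH <- H1 - H0
    divergent <- !is.finite(dH) || dH > 1000
    a <- if (is.finite(dH)) min(1, exp(-dH)) else 0
    if (stats::runif(1) < a) { q <- qn; st <- sn }

    if (it <= warmup) {
      adapt_iter <- adapt_iter + 1L
      Hbar <- (1 - 1 / (adapt_iter + t0)) * Hbar +
        (target_accept - a) / (adapt_iter + t0)
      log_eps <- mu_da - sqrt(adapt_iter) / gamma * Hbar
      w <- adapt_iter^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it > w_lo && it <= w_hi) warm_buf[it - w_lo, ] <- q
      if (it == w_hi) {
        v <- apply(warm_buf, 2, stats::var)
        minv <- (v * nrow(warm_buf) / (nrow(warm_buf) + 5) +
                   1e-3 * 5 / (nrow(warm_buf) + 5))
        # re-open step-size adaptation under the new metric
        eps <- find_reasonable_eps(lpg, q)
        mu_da <- log(10 * eps); Hbar <- 0; log_eps_bar <- 0
        adapt_iter <- 0L
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- q
      acc_sum <- acc_sum + a
      if (divergent) n_div <- n_div + 1L
    }
  }
  list(draws = draws, eps = eps, accept_rate = acc_sum / iter,
       divergences = n_div)
}

#' Fit a hierarchical RL model by Hamiltonian Monte Carlo
#'
#' Runs the configured number of chains from random prior-central
#' initializations, adapts step size and a diagonal metric during warm-up,
#' and computes split-chain Gelman-Rubin diagnostics. A warning (never a
#' silent pass) is raised if any parameter has R-hat > 1.1 or if any
#' post-warm-up divergence occurred.
#'
#' @param model an `rl_model` from [build_model()].
#' @param config a [sampler_config()].
#' @param seed integer seed; chain c uses `seed + c` so runs are
#'   reproducible.
#' @return an `rl_fit` object: unconstrained draws
#'   (`iter x chains x params`), per-parameter R-hat, divergence counts,
#'   acceptance rates and the originating model.
#' @export
fit_rl <- function(model, config = sampler_config(), seed = 1L) {
  stopifnot(inherits(model, "rl_model"), inherits(config, "sampler_config"))
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + ch)
    q0 <- model$init()
    st <- model$logp_grad(q0)
    tries <- 0L
    while (!is.finite(st$lp) && tries < 20L) {
      q0 <- model$init(); st <- model$logp_grad(q0); tries <- tries + 1L
    }
    if (!is.finite(st$lp))
      stop("non-finite log-density at initialization; parameters: ",
           paste(utils::head(model$param_names[!is.finite(st$grad)], 5),
                 collapse = ", "))
    chains[[ch]] <- run_hmc_chain(model$logp_grad, q0, config$warmup,
                                  config$iter, config$max_leapfrog,
                                  config$target_accept)
  }
  draws <- array(NA_real_,
                 dim = c(config$iter, config$chains, model$n_params),
                 dimnames = list(NULL, NULL, model$param_names))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  rh <- apply(draws, 3, rhat_matrix)
  names(rh) <- model$param_names
  divs <- vapply(chains, `[[`, integer(1), "divergences")
  fit <- structure(list(draws = draws, model = model, config = config,
                        seed = seed, rhat = rh,
                        divergences = divs,
                        accept_rate = vapply(chains, `[[`, numeric(1),
                                             "accept_rate"),
                        step_size = vapply(chains, `[[`, numeric(1), "eps")),
                   class = "rl_fit")
  if (max(rh, na.rm = TRUE) > 1.1)
    warning(sprintf("convergence not reached: max R-hat = %.3f (%s)",
                    max(rh, na.rm = TRUE), names(which.max(rh))))
  if (sum(divs) > 0)
    warning(sum(divs), " divergent transitions after warm-up")
  fit
}

#' @export
print.rl_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("RL model fit (%s): %d chains x %d draws, %d parameters\n",
              x$model$variant, d[2], d[1], d[3]))
  cat(sprintf("  max R-hat %.3f; %d divergences; mean accept %.2f\n",
              max(x$rhat, na.rm = TRUE), sum(x$divergences),
              mean(x$accept_rate)))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param fit an `rl_fit`.
#' @param natural_scales if `TRUE` (default), log-scale standard
#'   deviations are exponentiated and renamed (`log_sigma_x` ->
#'   `sigma_x`); other parameters are already on their reporting scale.
#' @return matrix `(chains * iter) x params`.
#' @export
as_draws_matrix <- function(fit, natural_scales = TRUE) {
  stopifnot(inherits(fit, "rl_fit"))
  d <- dim(fit$draws)
  m <- matrix(aperm(fit$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(m) <- dimnames(fit$draws)[[3]]
  if (natural_scales) {
    is_log <- grepl("^log_sigma", colnames(m))
    m[, is_log] <- exp(m[, is_log])
    colnames(m)[is_log] <- sub("^log_", "", colnames(m)[is_log])
  }
  m
}
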