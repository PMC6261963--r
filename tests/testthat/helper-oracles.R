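# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# Q trajectory of a single symbol under a reward sequence (naive loop).
oracle_q_trajectory <- function(rewards, alpha_G, alpha_L, q0 = 0) {
  q <- q0
  out <- numeric(length(rewards))
  for (t in seq_along(rewards)) {
    pe <- rewards[t] - q
    if (pe > 0) q <- q + alpha_G * pe
    if (pe < 0) q <- q + alpha_L * pe
    out[t] <- q
  }
  out
}

# Pointwise choice log-likelihood by direct replay with explicit softmax.
# records: data.frame with task_label, pair_id, chosen_better, reward.
oracle_loglik <- function(records, alpha_G, alpha_L, beta) {
  out <- numeric(nrow(records))
  Q <- NULL
  cur_task <- NULL
  for (t in seq_len(nrow(records))) {
    if (is.null(cur_task) || records$task_label[t] != cur_task) {
      Q <- rep(0, 6)
      cur_task <- records$task_label[t]
    }
    p <- match(records$pair_id[t], c("AB", "CD", "EF"))
    better <- 2 * p - 1; worse <- 2 * p
    pa <- exp(Q[better] / beta) / (exp(Q[better] / beta) +
                                     exp(Q[worse] / beta))
    chosen <- if (records$chosen_better[t]) better else worse
    out[t] <- log(if (records$chosen_better[t]) pa else 1 - pa)
    pe <- records$reward[t] - Q[chosen]
    if (pe > 0) Q[chosen] <- Q[chosen] + alpha_G * pe
    if (pe < 0) Q[chosen] <- Q[chosen] + alpha_L * pe
  }
  out
}

# Exact raw importance-sampling leave-one-out estimate (no smoothing).
oracle_loo_is <- function(log_lik) {
  S <- nrow(log_lik)
  elpd_i <- vapply(seq_len(ncol(log_lik)), function(i) {
    w <- exp(-log_lik[, i])          # 1 / p(y_i | theta_s)
    log(sum(w * exp(log_lik[, i])) / sum(w))
  }, numeric(1))
  list(elpd_i = elpd_i, elpd = sum(elpd_i), looic = -2 * sum(elpd_i))
}

# Random small trial-record table for likelihood oracle checks.
random_records <- function(n_trials, seed) {
  set.seed(seed)
  data.frame(
    task_label = "task1_default",
    pair_id = sample(c("AB", "CD", "EF"), n_trials, replace = TRUE),
    chosen_better = sample(c(TRUE, FALSE), n_trials, replace = TRUE),
    reward = sample(0:1, n_trials, replace = TRUE),
    stringsAsFactors = FALSE)
}

# Small simulated cohort shared by several expensive tests.
tiny_cohort <- function(n_nhg = 3L, n_placebo = 3L, seed = 7L) {
  n <- c(NHG = n_nhg, placebo = n_placebo)
  simulate_cohort(recovery_cohort_spec(n_per_group = n[n > 0L], seed = seed))
}
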