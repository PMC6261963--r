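test_that("deviance identity holds in the no-variance limit", {
  ll <- matrix(rep(c(-0.7, -1.1, -0.3), each = 50), 50, 3)
  res <- psis_loo(ll)
  expect_equal(res$elpd_loo, sum(c(-0.7, -1.1, -0.3)))
  expect_equal(res$looic, -2 * sum(c(-0.7, -1.1, -0.3)))
  expect_equal(res$p_loo, 0, tolerance = 1e-10)
  # duplicating every observation doubles elpd
  res2 <- psis_loo(cbind(ll, ll))
  expect_equal(res2$elpd_loo, 2 * res$elpd_loo)
})

test_that("toy posteriors match the exact importance-sampling oracle", {
  set.seed(31)
  for (case in 1:6) {
    S <- sample(4:8, 1); N <- sample(2:5, 1)
    ll <- matrix(log(runif(S * N, 0.2, 0.9)), S, N)
    res <- psis_loo(ll, warn = FALSE)
    ora <- oracle_loo_is(ll)
    expect_equal(res$elpd_i, ora$elpd_i, tolerance = 1e-12)
    expect_equal(res$looic, ora$looic, tolerance = 1e-12)
  }
})

test_that("elpd_loo never exceeds the in-sample lpd", {
  set.seed(32)
  for (case in 1:5) {
    ll <- matrix(rnorm(400 * 20, mean = -1, sd = 0.5), 400, 20)
    res <- psis_loo(ll, warn = FALSE)
    lpd <- sum(apply(ll, 2, function(col)
      max(col) + log(mean(exp(col - max(col))))))
    expect_lte(res$elpd_loo, lpd + 1e-10)
    expect_gte(res$p_loo, -1e-10)
  }
})

test_that("model comparison ranks, flags and guards observation sets", {
  set.seed(33)
  ll <- matrix(rnorm(200 * 30, -1, 0.3), 200, 30)
  a <- psis_loo(ll, warn = FALSE)
  cmp <- compare_loo(self1 = a, self2 = a)
  expect_equal(cmp$delta_looic, c(0, 0))
  expect_false(any(cmp$strong))

  # a clearly better model (higher likelihood everywhere)
  b <- psis_loo(ll + 1, warn = FALSE)
  cmp2 <- compare_loo(worse = a, better = b)
  expect_equal(cmp2$model[1], "better")
  expect_equal(cmp2$delta_looic[2], 2 * 30, tolerance = 5)
  expect_true(cmp2$strong[2])

  short <- psis_loo(ll[, 1:10], warn = FALSE)
  expect_error(compare_loo(a = a, b = short), "differing observation sets")
})

test_that("pointwise matrices agree with composed per-subject likelihoods", {
  co <- tiny_cohort(n_nhg = 2L, n_placebo = 0L, seed = 17)
  m <- build_model(co$trials, "M3_full")
  f <- suppressWarnings(fit_rl(m, sampler_config(chains = 2L, warmup = 120L,
                                                 iter = 60L,
                                                 max_leapfrog = 12L),
                               seed = 2))
  pm <- pointwise_matrix(f, max_draws = 4L)
  expect_equal(ncol(pm), nrow(co$trials))
  expect_true(all(is.finite(pm)))

  # a single draw's row equals concatenated trial_loglik calls
  draws <- as_draws_matrix(f, natural_scales = FALSE)[1, , drop = FALSE]
  nat <- m$natural_params(draws)
  row1 <- unlist(lapply(seq_along(m$data$subjects), function(i) {
    id <- m$data$subjects[i]
    unlist(lapply(1:2, function(day) {
      rec <- m$data$trials[m$data$trials$subject_id == id &
                             m$data$trials$day == day, ]
      d <- 2L * (i - 1L) + day
      trial_loglik(rec, agent_params(nat$alpha_G[1, d], nat$alpha_L[1, d],
                                     nat$beta[1, d]))
    }))
  }))
  res <- placeboRL:::rl_loglik_grad_cpp(
    m$data$pair, m$data$chosen, m$data$reward, m$data$seg_start,
    m$data$seg_len, m$set_of_seg - 1L,
    nat$alpha_G[1, ], nat$alpha_L[1, ], nat$beta[1, ])
  expect_equal(res$pointwise, unname(row1), tolerance = 1e-10)
})
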