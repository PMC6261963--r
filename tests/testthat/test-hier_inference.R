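test_that("model variants expose the documented parameter structure", {
  co <- tiny_cohort(n_nhg = 2L, n_placebo = 2L)
  S <- 4L
  m3 <- build_model(co$trials, "M3_full")
  # 3 mu + 3 sigma + 3 day effects + 3 placebo effects + sigma_b + 6 z
  # per subject (3 params x 2 days)
  expect_equal(m3$n_params, 3L + 3L + 3L + 3L + 1L + 6L * S)
  expect_true(all(c("mu_alphaG", "mu_alphaL", "mu_beta", "b_alphaG",
                    "b_beta_placebo", "log_sigma_b") %in% m3$param_names))

  m1 <- build_model(co$trials, "M1_single_alpha")
  expect_equal(m1$n_params, 2L + 2L + 2L * S)
  expect_false(any(grepl("^b_", m1$param_names)))

  m2 <- build_model(co$trials, "M2_day_group")
  expect_equal(m2$n_params, 2L + 2L + 2L + 2L + 1L + 4L * S)

  # a single-group (NHG) cohort has day effects but no group effects
  nhg <- simulate_cohort(recovery_cohort_spec(n_per_group = c(NHG = 2L),
                                              seed = 3))
  mn <- build_model(nhg$trials, "M3_full")
  expect_true("b_alphaG" %in% mn$param_names)
  expect_false(any(grepl("b_alphaG_", mn$param_names)))
})

test_that("joint log-density gradient matches finite differences", {
  co <- tiny_cohort(n_nhg = 2L, n_placebo = 2L)
  for (v in c("M3_full", "M2_day_group", "M1_single_alpha")) {
    for (shrink in if (v == "M1_single_alpha") FALSE else c(FALSE, TRUE)) {
      m <- build_model(co$trials, v, shrink_day_effects = shrink)
      set.seed(11)
      q <- m$init()
      st <- m$logp_grad(q)
      expect_true(is.finite(st$lp))
      fd <- vapply(seq_len(m$n_params), function(i) {
        h <- 1e-6; qp <- q; qm <- q
        qp[i] <- q[i] + h; qm[i] <- q[i] - h
        (m$logp_grad(qp)$lp - m$logp_grad(qm)$lp) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(fd - st$grad)), 1e-4)
    }
  }
})

test_that("model log-density is invariant to subject order", {
  co <- tiny_cohort(n_nhg = 2L, n_placebo = 2L)
  m <- build_model(co$trials, "M3_full")
  # reverse subject order in the input table
  rev_ids <- rev(unique(co$trials$subject_id))
  tr2 <- co$trials[order(match(co$trials$subject_id, rev_ids)), ]
  m2 <- build_model(tr2, "M3_full")
  set.seed(5)
  q <- m$init()
  # permute the per-subject-day z blocks to match the reversed order
  q2 <- q
  perm <- match(m2$data$subjects, m$data$subjects)
  for (k in seq_len(m$K)) {
    zk <- matrix(q[m$idx$z[, k]], nrow = 2)   # days x subjects
    q2[m2$idx$z[, k]] <- as.vector(zk[, perm])
  }
  expect_equal(m2$logp_grad(q2)$lp, m$logp_grad(q)$lp, tolerance = 1e-10)
})

test_that("prior predictive matches the implied-prior shape", {
  set.seed(8)
  n <- 20000
  pr <- prior_config()
  mu_a <- rnorm(n, pr$mu_alpha[1], pr$mu_alpha[2])
  sig_a <- abs(pr$sigma_alpha$scale * rcauchy(n))
  alpha <- to_natural(rnorm(n, mu_a, sig_a))
  expect_gt(mean(alpha < 0.5), 0.6)   # learning-rate mass below 0.5

  mu_b <- rnorm(n, pr$mu_beta[1], pr$mu_beta[2])
  sig_b <- abs(rnorm(n, 0, pr$sigma_beta$scale))
  beta <- to_natural_beta(rnorm(n, mu_b, sig_b))
  expect_gt(mean(beta < 2), 0.9)      # values above 2 are unrealistic
})

test_that("split-chain R-hat flags separation and passes good chains", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_true(rhat(good) >= 1 - 1e-8 && rhat(good) < 1.05)
  bad <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(rhat(bad), 1.1)
  const <- matrix(1, 100, 4)
  expect_equal(rhat(const), 1)
  expect_error(rhat(matrix(rnorm(10), 5, 2)[, 1, drop = FALSE]),
               "two chains")
  # trending chains are caught by splitting
  trend <- matrix(rep(seq(0, 5, length.out = 500), 4), 500, 4)
  expect_gt(rhat(trend), 1.1)
})

test_that("highest-density intervals behave on known shapes", {
  set.seed(2)
  x <- rnorm(100000)
  h <- hdi(x, 0.95)
  expect_equal(h[1], -1.96, tolerance = 0.05)
  expect_equal(h[2], 1.96, tolerance = 0.05)

  expect_equal(unname(hdi(rep(3.3, 60))), c(3.3, 3.3))

  e <- rexp(100000)
  he <- hdi(e, 0.95)
  expect_lt(he[1], 0.02)              # HDI hugs the mode at zero
  expect_lt(he[2], quantile(e, 0.97)) # narrower than central interval
  expect_error(hdi(rnorm(10)), "at least 50")
  expect_error(hdi(x, mass = 1.2))
})

test_that("a short fit is reproducible and structurally sound", {
  co <- tiny_cohort(n_nhg = 3L, n_placebo = 0L, seed = 13)
  m <- build_model(co$trials, "M1_single_alpha")
  cfg <- sampler_config(chains = 2L, warmup = 150L, iter = 100L,
                        max_leapfrog = 16L)
  f1 <- suppressWarnings(fit_rl(m, cfg, seed = 4))
  f2 <- suppressWarnings(fit_rl(m, cfg, seed = 4))
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws), c(100L, 2L, m$n_params))
  expect_named(f1$rhat, m$param_names)
  # split-chain R-hat has a small-sample floor of sqrt((n-1)/n)
  expect_true(all(f1$rhat >= sqrt(1 - 1 / 50) - 1e-8))
  expect_true(all(f1$accept_rate > 0.2))
  # posterior draws transform to valid natural-scale parameters
  nat <- m$natural_params(as_draws_matrix(f1, natural_scales = FALSE))
  expect_true(all(nat$alpha_G > 0 & nat$alpha_G < 1))
  expect_true(all(nat$beta > 0))
})

test_that("effect summaries have the group-by-parameter layout", {
  co <- tiny_cohort(n_nhg = 2L, n_placebo = 2L, seed = 21)
  m <- build_model(co$trials, "M3_full")
  f <- suppressWarnings(fit_rl(m, sampler_config(chains = 2L, warmup = 150L,
                                                 iter = 100L,
                                                 max_leapfrog = 16L),
                               seed = 9))
  tab <- summarize_effects(f)
  expect_setequal(unique(tab$group), c("NHG", "placebo"))
  expect_setequal(unique(tab$parameter), c("alphaG", "alphaL", "beta"))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))

  m1 <- build_model(co$trials, "M1_single_alpha")
  f1 <- suppressWarnings(fit_rl(m1, sampler_config(chains = 2L,
                                                   warmup = 150L,
                                                   iter = 100L,
                                                   max_leapfrog = 16L),
                                seed = 9))
  expect_error(summarize_effects(f1), "no day/group effects")
})
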