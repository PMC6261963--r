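test_that("value update follows the asymmetric learning rule", {
  p <- agent_params(0.5, 0.2, 1)
  expect_equal(q_update(0, 1, p), 0.5)
  expect_equal(q_update(0.5, 0, p), 0.4)
  p0 <- agent_params(0, 0, 1)
  expect_equal(q_update(0.37, 1, p0), 0.37)
  expect_equal(q_update(0.37, 0, p0), 0.37)
  # zero prediction error updates nothing under either rate
  p1 <- agent_params(0.9, 0.9, 1)
  expect_equal(q_update(1, 1, p1), 1)

  expect_error(agent_params(-0.1, 0.5, 1), "alpha_G")
  expect_error(agent_params(0.5, 1.2, 1), "alpha_L")
  expect_error(agent_params(0.5, 0.5, 0), "beta")
})

test_that("20-step value trajectories match the naive loop oracle", {
  set.seed(101)
  for (case in 1:5) {
    rewards <- sample(0:1, 20, replace = TRUE)
    p <- agent_params(0.3, 0.1, 1)
    q <- 0
    traj <- numeric(20)
    for (t in 1:20) {
      q <- q_update(q, rewards[t], p)
      traj[t] <- q
    }
    expect_equal(traj, oracle_q_trajectory(rewards, 0.3, 0.1),
                 tolerance = 1e-12)
    # boundedness: rewards in {0,1} and rates in [0,1] keep Q in [0,1]
    expect_true(all(traj >= 0 & traj <= 1))
  }
})

test_that("softmax choice rule: worked example, symmetry, limits", {
  # perfect knowledge of the easiest pair at beta = 2 gives only ~0.57
  expect_equal(round(choice_prob(0.8, 0.2, 2), 2), 0.57)
  expect_equal(choice_prob(0.8, 0.2, 2),
               exp(0.8 / 2) / (exp(0.8 / 2) + exp(0.2 / 2)))
  expect_equal(choice_prob(0.3, 0.3, 0.01), 0.5)
  expect_equal(choice_prob(0.8, 0.2, 1e-4), 1, tolerance = 1e-10)
  # normalization to machine precision, including extreme ratios
  for (b in c(1e-3, 0.2, 2, 1e3)) {
    pa <- choice_prob(0.9, 0.1, b)
    pb <- choice_prob(0.1, 0.9, b)
    expect_equal(pa + pb, 1)
  }
  expect_error(choice_prob(1, 0, -1), "beta")
})

test_that("simulated subjects follow their group's schedule", {
  p <- agent_params(0.3, 0.3, 0.2)
  nhg <- simulate_subject(p, p, "NHG", seed = 1)
  expect_equal(sum(nhg$day == 1), 240L)
  expect_equal(sum(nhg$day == 2), 240L)
  expect_setequal(unique(nhg$task_label), c("task1_default", "task3_default"))

  pl <- simulate_subject(p, p, "placebo", seed = 1)
  expect_equal(sum(pl$day == 1), 360L)
  expect_equal(sum(pl$task_label == "task2_placebo"), 120L)
  nc <- simulate_subject(p, p, "nocebo_control", seed = 1)
  expect_equal(sum(nc$task_label == "task2_nocebo"), 120L)
  expect_true(all(nc$rt_ms <= 1700))

  expect_identical(simulate_subject(p, p, "placebo", seed = 9),
                   simulate_subject(p, p, "placebo", seed = 9))
})

test_that("non-learning and noise-dominated agents perform at chance", {
  p0 <- agent_params(0, 0, 1)
  set.seed(2)
  acc0 <- mean(replicate(20, {
    s <- simulate_subject(p0, p0, "NHG", rt = NULL)
    mean(s$chosen_better)
  }))
  expect_lt(abs(acc0 - 0.5), 0.02)

  pn <- agent_params(0.5, 0.5, 1000)
  set.seed(3)
  accn <- mean(replicate(20, {
    s <- simulate_subject(pn, pn, "NHG", rt = NULL)
    mean(s$chosen_better)
  }))
  expect_lt(abs(accn - 0.5), 0.02)
})

test_that("easier pairs are learned better than harder ones", {
  p <- agent_params(0.3, 0.3, 0.2)
  set.seed(4)
  d <- make_design("task1_default")
  accs <- t(replicate(500, {
    s <- generate_session(d)
    sim <- placeboRL:::rl_simulate_cpp(match(s$pair_id, c("AB", "CD", "EF")) - 1L,
                                       d$pairs$p_better, d$pairs$p_worse,
                                       0.3, 0.3, 0.2)
    tapply(sim$chose_better, s$pair_id, mean)
  }))
  expect_gt(mean(accs[, "AB"]), mean(accs[, "EF"]))
})

test_that("cohort generation respects the hierarchy and the design", {
  # degenerate hierarchy: zero spread pins every subject at the group value
  sp <- cohort_spec(n_per_group = c(NHG = 3L),
                    hyper = hyper_params(mu_alphaG = 0, mu_alphaL = 0,
                                         mu_beta = 0, sigma_alphaG = 0,
                                         sigma_alphaL = 0, sigma_beta = 0),
                    effects = group_effects(b = c(alpha_G = 0, alpha_L = 0,
                                                  beta = 0)),
                    subjective_probs = NULL, rt = NULL, seed = 5)
  co <- simulate_cohort(sp)
  expect_true(all(co$true_params$alpha_G == 0))   # probit scale
  expect_true(all(to_natural(co$true_params$alpha_G) == 0.5))
  expect_true(all(to_natural_beta(co$true_params$beta) == 1))

  # five-group layout: day-1/day-2 trial counts per subject
  sp5 <- cohort_spec(n_per_group = stats::setNames(rep(1L, 5),
                                                   placeboRL:::RL_GROUPS),
                     seed = 6)
  co5 <- simulate_cohort(sp5)
  cnt <- with(co5$trials, tapply(day, list(group, day), length))
  expect_equal(unname(cnt["NHG", ]), c(240L, 240L))
  expect_equal(unname(cnt["placebo", ]), c(360L, 240L))
  expect_equal(unname(cnt["nocebo_control", ]), c(360L, 240L))
  expect_true(all(co5$trials$reward %in% 0:1))
  # subjective reports: one per question for manipulated groups only
  expect_equal(nrow(co5$subjective), 8L)
  expect_false("NHG" %in% co5$subjective$group)
})
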