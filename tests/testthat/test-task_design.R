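test_that("built-in designs carry the study's contingencies and lengths", {
  d1 <- make_design("task1_default")
  expect_equal(n_trials(d1), 240L)
  expect_equal(d1$n_blocks, 4L)
  expect_equal(d1$pairs$p_better, c(0.80, 0.70, 0.60))
  expect_equal(d1$pairs$p_worse, c(0.20, 0.30, 0.40))

  dp <- make_design("task2_placebo")
  expect_equal(n_trials(dp), 120L)
  expect_equal(dp$pairs$p_better, c(0.90, 0.90, 0.80))

  dn <- make_design("task2_nocebo")
  expect_equal(n_trials(dn), 120L)
  expect_equal(dn$pairs$p_better, c(0.60, 0.60, 0.55))
  expect_equal(dn$pairs$p_worse, c(0.40, 0.40, 0.45))

  expect_equal(n_trials(make_design("task3_default")), 240L)
  expect_error(make_design("task9"), "valid labels")
  expect_error(session_design("x", 2, 20, c(0.5, 0.6, 0.7), c(0.5, 0.4, 0.3)),
               "p_worse < p_better")
  expect_error(session_design("x", 2, 3, c(0.8, 0.7, 0.6), c(0.2, 0.3, 0.4)),
               "even")
})

test_that("generated schedules are counterbalanced permutations", {
  for (seed in c(1L, 23L, 999L)) {
    for (label in c("task1_default", "task2_nocebo")) {
      d <- make_design(label)
      s <- generate_session(d, seed = seed)
      expect_equal(nrow(s), n_trials(d))
      expect_equal(s$trial_in_session, seq_len(nrow(s)))
      # each pair appears reps times per block, half of them better-left
      counts <- table(s$block, s$pair_id)
      expect_true(all(counts == d$reps_per_pair_per_block))
      lefts <- tapply(s$better_on_left, list(s$block, s$pair_id), sum)
      expect_true(all(lefts == d$reps_per_pair_per_block / 2))
    }
  }
  # per-pair totals for the default task: 4 blocks x 20 = 80
  s <- generate_session(make_design("task1_default"), seed = 5)
  expect_true(all(table(s$pair_id) == 80L))
})

test_that("smallest counterbalanced schedule and determinism", {
  d <- session_design("mini", n_blocks = 1, reps_per_pair_per_block = 2,
                      p_better = c(0.8, 0.7, 0.6), p_worse = c(0.2, 0.3, 0.4))
  s <- generate_session(d, seed = 3)
  expect_equal(nrow(s), 6L)
  agg <- tapply(s$better_on_left, s$pair_id, sum)
  expect_true(all(agg == 1L)) # each pair once left, once right

  expect_identical(generate_session(make_design("task1_default"), seed = 42),
                   generate_session(make_design("task1_default"), seed = 42))
})

test_that("feedback sampling follows the pair contingencies", {
  deg <- session_design("deg", 1, 2, p_better = c(1, 1, 1),
                        p_worse = c(0, 0, 0))
  expect_true(all(sample_feedback(deg, rep("AB", 50), rep(TRUE, 50)) == 1L))
  expect_true(all(sample_feedback(deg, rep("AB", 50), rep(FALSE, 50)) == 0L))

  d <- make_design("task1_default")
  set.seed(11)
  r <- sample_feedback(d, rep("AB", 10000), rep(TRUE, 10000))
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(mean(r) - 0.8), 3 * se)
  # law of large numbers on the worse symbol of the hardest pair
  r2 <- sample_feedback(d, rep("EF", 10000), rep(FALSE, 10000))
  expect_lt(abs(mean(r2) - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  expect_error(sample_feedback(d, "ZZ", TRUE), "unknown pair_id")
})
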