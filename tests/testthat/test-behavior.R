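# Small synthetic regression datasets keep the JAGS fits in these tests
# fast; they are generated directly from the regression models, not via
# the RL simulator, so that the true coefficients are known exactly.

make_glm_trials <- function(n_subj = 20, n_trial = 60, b_day = 0,
                            b0 = 0.4, sd_subj = 0.3, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subj), function(s) {
    u <- rnorm(1, 0, sd_subj)
    d <- expand.grid(day = 1:2, trial_in_session = seq_len(n_trial))
    d$pair_id <- sample(c("AB", "CD", "EF"), nrow(d), replace = TRUE)
    eta <- b0 + u + b_day * (d$day == 2)
    d$chosen_better <- runif(nrow(d)) < plogis(eta)
    d$subject_id <- sprintf("P%02d", s)
    d$group <- "NHG"
    d$reward <- 1L
    d$rt_ms <- 600
    d
  })
  do.call(rbind, rows)
}

test_that("design construction codes factors and z-scores as stated", {
  tr <- make_glm_trials(n_subj = 2, n_trial = 10)
  d <- build_design(tr, "accuracy")
  expect_equal(mean(d$trial_z), 0, tolerance = 1e-12)
  expect_equal(sd(d$trial_z), 1, tolerance = 1e-12)
  expect_equal(levels(d$pair), c("AB", "CD", "EF"))
  expect_equal(levels(d$group)[1], "NHG")
  # baseline rows (pair AB, day 1, NHG) have zero dummies in the full design
  tr2 <- rbind(tr, within(make_glm_trials(n_subj = 2, n_trial = 10), {
    subject_id <- sub("P", "R", subject_id); group <- "nocebo"
  }))
  d2 <- build_design(tr2, "accuracy")
  X <- model.matrix(placeboRL:::behavior_formula("group_day"), d2)
  base_rows <- d2$pair == "AB" & d2$day01 == 0 & d2$group == "NHG"
  non_int <- setdiff(colnames(X), c("(Intercept)", "trial_z"))
  expect_true(all(X[base_rows, grep("pair|day|group", non_int,
                                    value = TRUE)] == 0))
  expect_error(build_design(tr[, -3], "accuracy"), "missing columns")

  # hand-built oracle for a toy design matrix
  toy <- tr[c(1, 25, 40), ]
  dt <- build_design(toy, "accuracy")
  Xt <- model.matrix(placeboRL:::behavior_formula("base"), dt)
  zt <- (toy$trial_in_session - mean(toy$trial_in_session)) /
    sd(toy$trial_in_session)
  manual <- cbind(1, zt, toy$pair_id == "CD", toy$pair_id == "EF",
                  toy$day == 2, zt * (toy$pair_id == "CD"),
                  zt * (toy$pair_id == "EF"), zt * (toy$day == 2))
  expect_equal(matrix(as.numeric(Xt), nrow(Xt)),
               matrix(as.numeric(manual), nrow(manual)))
})

test_that("logistic regression recovers a known day effect and nulls", {
  tr <- make_glm_trials(n_subj = 20, n_trial = 50, b_day = 0.5, seed = 5)
  d <- build_design(tr, "accuracy")
  f <- fit_behavior(d, level = "base", chains = 2, warmup = 300,
                    iter = 600, seed = 2)
  s <- behavior_summary(f)
  day <- s[s$term == "day01", ]
  expect_gt(0.5, day$lower); expect_lt(0.5, day$upper)
  # no pair structure was simulated: those effects cover zero
  for (term in c("pairCD", "pairEF", "trial_z")) {
    row <- s[s$term == term, ]
    expect_true(row$lower <= 0 & row$upper >= 0)
  }
  expect_true(max(f$rhat) < 1.2)
})

test_that("contrasts difference the day-by-group coefficients", {
  tr <- rbind(make_glm_trials(6, 30, b_day = 0.3, seed = 7),
              within(make_glm_trials(6, 30, b_day = 0.6, seed = 8), {
                subject_id <- sub("P", "Q", subject_id)
                group <- "placebo"
              }))
  d <- build_design(tr, "accuracy")
  f <- suppressWarnings(
    fit_behavior(d, level = "group_day", chains = 2, warmup = 250,
                 iter = 400, seed = 3))
  self <- contrast(f, "placebo", "placebo")
  expect_true(all(self$draws == 0))
  ab <- contrast(f, "placebo", "NHG")
  ba <- contrast(f, "NHG", "placebo")
  expect_equal(ab$draws, -ba$draws)   # antisymmetry, draw by draw
  expect_error(contrast(f, "placebo", "nocebo"), "no day:group")
  base_fit <- suppressWarnings(fit_behavior(d, level = "base", chains = 2,
                                            warmup = 150, iter = 150,
                                            seed = 3))
  expect_error(contrast(base_fit, "placebo", "NHG"),
               "day:group interaction")
})

test_that("RT regression runs with the Gaussian likelihood", {
  tr <- make_glm_trials(8, 30, seed = 9)
  set.seed(10)
  tr$rt_ms <- 800 - 60 * (tr$day == 2) + rnorm(nrow(tr), 0, 80)
  d <- build_design(tr, "rt")
  f <- fit_behavior(d, level = "base", chains = 2, warmup = 250,
                    iter = 400, seed = 4)
  s <- behavior_summary(f)
  day <- s[s$term == "day01", ]
  expect_gt(-60, day$lower); expect_lt(-60, day$upper)
})

test_that("subjective softmax regression and implied probabilities", {
  set.seed(12)
  groups <- rep(c("placebo", "nocebo", "placebo_control", "nocebo_control"),
                each = 16)
  resp <- do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(subject_id = sprintf("S%03d", i), group = groups[i],
               question = c("expected", "perceived"),
               response = sample(c("decline", "neutral", "improve"), 2,
                                 replace = TRUE,
                                 prob = if (groups[i] == "placebo")
                                   c(0.05, 0.25, 0.70) else
                                     if (groups[i] == "nocebo")
                                       c(0.70, 0.22, 0.08) else
                                         c(1, 1, 1) / 3),
               stringsAsFactors = FALSE)))
  f <- fit_subjective(resp, chains = 2, warmup = 300, iter = 500, seed = 6)
  p_pl <- implied_probabilities(f, "placebo", "expected")
  # per-draw triples sum to one exactly
  expect_equal(unname(rowSums(attr(p_pl, "draws"))),
               rep(1, nrow(attr(p_pl, "draws"))))
  expect_equal(sum(p_pl$mean), 1, tolerance = 1e-9)
  expect_true(all(p_pl$lower >= 0 & p_pl$upper <= 1))
  # the modal expected response of the placebo arm is "improve"
  expect_equal(p_pl$response[which.max(p_pl$mean)], "improve")
  p_no <- implied_probabilities(f, "nocebo", "expected")
  expect_equal(p_no$response[which.max(p_no$mean)], "decline")
  # near-uniform cells sit near 1/3
  p_cc <- implied_probabilities(f, "placebo_control", "expected")
  expect_true(all(abs(p_cc$mean - 1 / 3) < 0.2))

  # reference-category invariance: shifting all category coefficients by
  # the decline coefficients (making decline the reference) leaves the
  # implied probabilities unchanged
  draws <- attr(p_pl, "draws")
  x <- model.matrix(placeboRL:::subjective_formula,
                    placeboRL:::subjective_design_row("placebo", "expected"))
  flat <- matrix(f$draws, dim(f$draws)[1] * dim(f$draws)[2], dim(f$draws)[3])
  colnames(flat) <- dimnames(f$draws)[[3]]
  P <- length(f$coef_names)
  eta_dec <- drop(flat[, paste0("decline_", 1:P)] %*% t(x))
  eta_imp <- drop(flat[, paste0("improve_", 1:P)] %*% t(x))
  e2 <- cbind(exp(eta_dec - eta_dec), exp(-eta_dec), exp(eta_imp - eta_dec))
  p2 <- e2 / rowSums(e2)
  expect_equal(unname(draws), unname(p2), tolerance = 1e-10)

  dup <- rbind(resp, resp[1, ])
  expect_error(fit_subjective(dup), "one response per")
})
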