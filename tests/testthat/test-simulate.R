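test_that("zero population SDs make every participant equal to the means", {
  pop <- small_pop(alpha_mem = c(0.3, 0), beta1_mem = c(0.2, 0),
                   b0_choice = c(0.5, 0), gamma1_est = c(0.4, 0),
                   rho_bias_belief = 0)
  p <- draw_participant_params(pop, seed = 31)
  expect_equal(p$alpha_mem, 0.3)
  expect_equal(p$beta1_mem, 0.2)
  expect_equal(p$b0_choice, 0.5)
  expect_equal(p$gamma1_est, 0.4)
})

test_that("perfect bias-belief correlation aligns the standardized draws", {
  pop <- small_pop(b0_choice = c(0, 1), gamma1_est = c(0, 1),
                   rho_bias_belief = 1)
  set.seed(32)
  draws <- t(replicate(50, {
    p <- draw_participant_params(pop)
    c(p$b0_choice, p$gamma1_est)
  }))
  expect_equal(draws[, 1], draws[, 2], tolerance = 1e-12)
})

test_that("the bias-belief correlation is recovered across many draws", {
  pop <- small_pop(b0_choice = c(0.5, 0.6), gamma1_est = c(0.3, 0.25),
                   rho_bias_belief = 0.4)
  set.seed(33)
  draws <- t(replicate(10000, {
    p <- draw_participant_params(pop)
    c(p$b0_choice, p$gamma1_est)
  }))
  expect_equal(cor(draws[, 1], draws[, 2]), 0.4, tolerance = 0.02)
})

test_that("an invalid correlation is rejected", {
  expect_error(population_params(rho_bias_belief = 1.2),
               class = "membias_config_error")
  expect_error(population_params(beta1_mem = c(0, -1)),
               class = "membias_config_error")
})

test_that("saturated recall leaves no one-remembered trials", {
  set.seed(34)
  ratings <- random_ratings(16)
  d <- build_trial_sets(ratings, small_config())
  pop <- small_pop()
  params <- draw_participant_params(pop)
  params$alpha_mem <- 20
  params$beta1_mem <- 0
  params$beta2_mem <- 0
  params$p_miss <- 0
  rec <- simulate_participant(params, ratings, d)
  expect_true(all(rec$recalls$correct == 1L))
  cls <- classify_decision_trials(rec$decisions, rec$recalls)
  expect_true(all(cls$trial_type == "both_remembered"))
})

test_that("an indifferent chooser picks the remembered option half the time", {
  set.seed(35)
  ratings <- random_ratings(16)
  d <- build_trial_sets(ratings, small_config())
  pop <- small_pop()
  chose_rem <- unlist(lapply(1:60, function(i) {
    params <- draw_participant_params(pop)
    params$alpha_mem <- 0
    params$beta1_mem <- 0
    params$beta2_mem <- 0
    params$b0_choice <- 0
    params$b1_choice <- 0
    params$p_miss <- 0
    rec <- simulate_participant(params, ratings, d)
    cls <- classify_decision_trials(rec$decisions, rec$recalls)
    one <- cls[cls$trial_type == "one_remembered", ]
    (one$choice == "a" & one$rem_a) | (one$choice == "b" & one$rem_b)
  }))
  expect_gt(length(chose_rem), 400)
  expect_equal(mean(chose_rem), 0.5, tolerance = 0.05)
})

test_that("recall-model coefficients are recovered from pooled simulations", {
  set.seed(36)
  ratings <- random_ratings(48)
  d <- build_trial_sets(ratings)
  pop <- population_params()
  params <- draw_participant_params(pop)
  params$alpha_mem <- 0
  params$beta1_mem <- 0.3
  params$beta2_mem <- 0.2
  # pool recall outcomes from repeated runs of the same participant (~5,000)
  reps <- lapply(1:35, function(i) simulate_participant(params, ratings, d))
  recalls <- do.call(rbind, lapply(reps, function(r) r$recalls))
  vt <- membias:::value_terms(list(design = reps[[1]]$design, ratings = ratings))
  X <- cbind(1, z = unname(vt$z[recalls$snack_id]), q = unname(vt$q[recalls$snack_id]))
  fit <- fit_logistic_mle(X, recalls$correct)
  expect_lt(max(abs(fit$coefficients - c(0, 0.3, 0.2))), 0.05)
  # and the fit agrees with an independent direct likelihood maximization
  expect_lt(max(abs(fit$coefficients - logistic_oracle(X, recalls$correct))),
            1e-5)
})

test_that("recall probability increases with value when only beta1 is positive", {
  set.seed(37)
  ratings <- random_ratings(48)
  d <- build_trial_sets(ratings)
  params <- draw_participant_params(population_params())
  params$alpha_mem <- 0
  params$beta1_mem <- 0.8
  params$beta2_mem <- 0
  reps <- do.call(rbind, lapply(1:30, function(i) {
    simulate_participant(params, ratings, d)$recalls
  }))
  vt <- membias:::value_terms(list(design = d$blocks, ratings = ratings))
  z <- unname(vt$z[reps$snack_id])
  lo <- mean(reps$correct[z < -0.5])
  mid <- mean(reps$correct[abs(z) <= 0.5])
  hi <- mean(reps$correct[z > 0.5])
  expect_true(lo < mid && mid < hi)
})

test_that("estimates stay within 0..6 and track k exactly in the noiseless case", {
  set.seed(38)
  coh <- small_cohort(n = 6, seed = 39)
  expect_true(all(coh$estimates$estimate %in% 0:6))
  # noiseless, value-free estimation is a deterministic function of k
  ratings <- random_ratings(16)
  d <- build_trial_sets(ratings, small_config())
  params <- draw_participant_params(small_pop())
  params$gamma1_est <- 0
  params$gamma2_est <- 0
  params$sigma_est <- 0
  params$gamma0_est <- 1
  params$gamma_perf <- 0.5
  rec <- simulate_participant(params, ratings, d)
  k <- tapply(rec$recalls$correct, rec$recalls$snack_id, sum)
  k <- k[rec$estimates$snack_id]
  expect_equal(rec$estimates$estimate,
               as.integer(pmin(pmax(round(1 + 0.5 * as.vector(k)), 0), 6)))
})

test_that("cohort simulation is deterministic under a seed", {
  c1 <- small_cohort(n = 3, seed = 40)
  c2 <- small_cohort(n = 3, seed = 40)
  for (tab in c("ratings", "design", "recalls", "decisions", "estimates")) {
    expect_identical(as.data.frame(c1[[tab]]), as.data.frame(c2[[tab]]))
  }
  expect_identical(as.data.frame(c1$true_params), as.data.frame(c2$true_params))
  expect_error(simulate_cohort(small_pop(), n = 0), class = "membias_config_error")
})
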