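test_that("standardization matches hand-computed cases", {
  expect_equal(standardize_values(c(2, 4, 6)), c(-1, 0, 1))
  expect_error(standardize_values(rep(3, 10)), class = "membias_degenerate_error")
  set.seed(41)
  z <- standardize_values(runif(24))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("the quadratic term is the restandardized square", {
  q <- quadratic_term(c(-1, 0, 1))
  expect_equal(q, c(1, -2, 1) / sqrt(3), tolerance = 1e-12)
  set.seed(42)
  z <- standardize_values(rnorm(30))
  expect_equal(quadratic_term(z), quadratic_term(-z))
  expect_equal(cor(quadratic_term(z), z^2), 1)
  expect_error(quadratic_term(c(-1, 1, -1, 1)), class = "membias_degenerate_error")
})

test_that("decision trials are classified by block-level recall, miss first", {
  recalls <- tibble::tibble(
    participant_id = "p1", block = 1L,
    snack_id = c("s1", "s2", "s3", "s4"), location = 1:4,
    correct = c(1L, 1L, 0L, 0L), strength = 0.5
  )
  decisions <- tibble::tibble(
    participant_id = "p1", block = 1L, trial = 1:4,
    snack_a = c("s1", "s1", "s3", "s1"),
    snack_b = c("s2", "s3", "s4", "s3"),
    choice = c("a", "b", "a", "missed")
  )
  cls <- classify_decision_trials(decisions, recalls)
  expect_equal(cls$trial_type,
               c("both_remembered", "one_remembered", "both_forgotten", "missed"))
  bad <- decisions
  bad$snack_b[1] <- "s9"
  expect_error(classify_decision_trials(bad, recalls),
               class = "membias_validation_error")
})

test_that("one-remembered frequency matches 2p(1-p) at p = 0.5", {
  set.seed(43)
  ratings <- random_ratings(16)
  d <- build_trial_sets(ratings, small_config())
  params <- draw_participant_params(small_pop())
  params$alpha_mem <- 0
  params$beta1_mem <- 0
  params$beta2_mem <- 0
  params$p_miss <- 0
  frac <- replicate(40, {
    rec <- simulate_participant(params, ratings, d)
    cls <- classify_decision_trials(rec$decisions, rec$recalls)
    mean(cls$trial_type == "one_remembered")
  })
  expect_equal(mean(frac), 0.5, tolerance = 0.03)
})

test_that("intercept-only logistic fits have the closed-form solution", {
  y <- c(rep(1, 6), rep(0, 6))
  f <- fit_logistic_mle(matrix(1, 12), y)
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-10)
  y <- c(rep(1, 9), rep(0, 3))
  f <- fit_logistic_mle(matrix(1, 12), y)
  expect_equal(unname(f$coefficients), log(3), tolerance = 1e-8)
  expect_equal(f$deviance, -2 * (9 * log(0.75) + 3 * log(0.25)), tolerance = 1e-8)
})

test_that("the IRLS fit matches the independent optimizer on random problems", {
  set.seed(44)
  for (i in 1:10) {
    n <- 200L
    X <- cbind(1, rnorm(n), rnorm(n))
    b <- runif(3, -1, 1)
    y <- rbinom(n, 1, plogis(drop(X %*% b)))
    fit <- fit_logistic_mle(X, y)
    expect_equal(unname(fit$coefficients), logistic_oracle(X, y),
                 tolerance = 1e-5)
  }
})

test_that("separation is flagged and collinearity rejected", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- fit_logistic_mle(cbind(1, x), y)
  expect_true(f$separation)
  expect_error(fit_logistic_mle(cbind(1, x, 2 * x), y),
               class = "membias_fit_error", regexp = "collinear")
})

test_that("the corrected bias is the exact reparameterization of the fit", {
  coh <- small_cohort(n = 8, seed = 45)
  recs <- participant_records(coh)
  checked <- 0L
  for (rec in recs) {
    mb <- memory_bias(rec, corrected = FALSE, min_trials = 5)
    mbc <- memory_bias(rec, corrected = TRUE, min_trials = 5)
    if (!is.finite(mb$b0) || !is.finite(mbc$b0)) next
    expect_equal(mbc$b0, mb$b0 + mb$b1 * mb$mean_forgotten_z, tolerance = 1e-8)
    expect_equal(mbc$b1, mb$b1, tolerance = 1e-8)
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("the bias intercept is recovered from a large simulated fit", {
  set.seed(46)
  n <- 20000L
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 1 * z))
  f <- fit_logistic_mle(cbind(1, z), y)
  expect_equal(unname(f$coefficients), c(0.5, 1), tolerance = 0.03)
})

test_that("forgotten options are below average in value when beta1 > 0", {
  coh <- simulate_cohort(small_pop(beta1_mem = c(0.4, 0.1)), n = 12, seed = 47,
                         config = small_config())
  coefs <- participant_coefficients(coh, min_trials = 5)
  expect_lt(mean(coefs$mean_forgotten_z, na.rm = TRUE), 0)
})

test_that("exact linear estimation data is recovered exactly", {
  coh <- small_cohort(n = 1, seed = 48)
  rec <- participant_records(coh)[[1]]
  vt <- membias:::value_terms(rec)
  rec$estimates$estimate <- 3 + unname(vt$z[rec$estimates$snack_id])
  f <- value_dependency(rec, "estimation", "linear")
  expect_equal(unname(f$coefficients), c(3, 1), tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)
})

test_that("controlling for performance removes a pure-k estimation effect", {
  set.seed(49)
  coh <- small_cohort(n = 20, seed = 50,
                      pop = small_pop(gamma1_est = c(0, 0), gamma2_est = c(0, 0),
                                      gamma_perf = c(0.6, 0.05),
                                      sigma_est = c(0.3, 0)))
  coefs <- participant_coefficients(coh, min_trials = 5)
  # value coefficients conditional on k center on zero
  expect_equal(mean(coefs$est_on_value_ctrl, na.rm = TRUE), 0, tolerance = 0.06)
  # while the performance coefficient is clearly positive
  expect_gt(mean(coefs$est_on_perf, na.rm = TRUE), 0.3)
})

test_that("estimation cell means split by performance and value", {
  coh <- small_cohort(n = 1, seed = 51)
  rec <- participant_records(coh)[[1]]
  cells <- estimation_cell_means(rec)
  expect_setequal(unique(cells$value_group), c("below", "above"))
  expect_equal(sum(cells$n), nrow(rec$estimates))
  # estimates equal to k make the two value groups identical within k
  k <- tapply(rec$recalls$correct, rec$recalls$snack_id, sum)
  rec$estimates$estimate <- as.integer(k[rec$estimates$snack_id])
  cells <- estimation_cell_means(rec)
  filled <- cells[cells$n > 0, ]
  expect_equal(filled$mean_estimate, filled$k)
})

test_that("exclusion criteria drop the participants they should", {
  coh <- small_cohort(n = 6, seed = 52)
  # permissive criteria are the identity
  res <- apply_exclusions(coh, exclusion_criteria())
  expect_equal(participants(res$cohort), participants(coh))
  expect_equal(nrow(res$log), 0L)
  # constant ratings fail the rating-variance criterion
  bad <- coh
  bad$ratings$rating[bad$ratings$participant_id == "p002"] <- 5
  res <- apply_exclusions(bad, exclusion_criteria(min_rating_sd = 0.1))
  expect_false("p002" %in% participants(res$cohort))
  expect_true("min_rating_sd" %in% res$log$criterion[res$log$participant_id == "p002"])
  # a recall-rate floor removes low-recall participants
  pop_low <- small_pop(alpha_mem = c(-3, 0))
  low <- simulate_cohort(pop_low, n = 3, seed = 53, config = small_config())
  res <- apply_exclusions(low, exclusion_criteria(recall_rate_min = 0.2))
  expect_equal(nrow(res$cohort$ratings), 0L)
})
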