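test_that("pure mediation yields a1 = 1, b3 = 1, c1 = 0", {
  set.seed(71)
  z <- standardize_values(rnorm(200))
  q <- quadratic_term(z)
  perf <- 0.6 * z + rnorm(200, 0, 1e-6)  # hairline noise to keep X full rank
  dat <- tibble::tibble(z = z, q = q, k = perf, estimate = perf)
  p <- fit_participant_path(dat)
  expect_equal(p$a1, 1, tolerance = 1e-4)
  expect_equal(p$b3, 1, tolerance = 1e-4)
  expect_equal(p$c1, 0, tolerance = 1e-4)
  expect_equal(p$indirect_z, p$a1 * p$b3)
})

test_that("b3 vanishes when estimation is independent of performance given value", {
  set.seed(72)
  n <- 5000L
  z <- standardize_values(rnorm(n))
  q <- quadratic_term(z)
  dat <- tibble::tibble(z = z, q = q,
                        k = z + rnorm(n), estimate = z + rnorm(n))
  p <- fit_participant_path(dat)
  expect_equal(p$b3, 0, tolerance = 0.04)
  expect_gt(p$a1, 0.5)
  expect_gt(p$c1, 0.5)
})

test_that("the Cochran decomposition holds exactly per participant", {
  coh <- small_cohort(n = 8, seed = 73)
  recs <- participant_records(coh)
  for (rec in recs) {
    vt <- membias:::value_terms(rec)
    et <- membias:::estimation_table(rec, vt)
    p <- fit_participant_path(et)
    if (!is.finite(p$a1)) next
    est_s <- standardize_values(et$estimate)
    reduced <- fit_linear_ml(cbind(1, z = et$z, q = et$q), est_s)
    expect_equal(unname(reduced$coefficients["z"]), p$c1 + p$b3 * p$a1,
                 tolerance = 1e-10)
    expect_equal(unname(reduced$coefficients["q"]), p$c2 + p$b3 * p$a2,
                 tolerance = 1e-10)
  }
})

test_that("zero-variance path variables are flagged missing, not fatal", {
  dat <- tibble::tibble(z = standardize_values(1:10),
                        q = quadratic_term(standardize_values(1:10)),
                        k = rep(3, 10), estimate = 1:10)
  p <- fit_participant_path(dat)
  expect_true(is.na(p$a1))
  expect_match(p$reason, "zero variance")
})

test_that("the strength mediator enters as a parallel path", {
  coh <- small_cohort(n = 4, seed = 74)
  paths <- path_coefficients(coh, include_strength = TRUE)
  expect_true(all(c("s1", "b_str", "indirect_z_strength") %in% names(paths)))
  ok <- is.finite(paths$s1)
  expect_gt(sum(ok), 0)
  expect_equal(paths$indirect_z_strength[ok], (paths$s1 * paths$b_str)[ok])
})

test_that("group path tests behave under symmetry and degeneracy", {
  paths <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:10),
    a1 = c(-5:-1, 1:5) / 5
  )
  res <- group_path_tests(paths)
  expect_equal(res$statistic[res$coefficient == "a1"], 0, tolerance = 1e-12)
  degenerate <- tibble::tibble(participant_id = c("a", "b", "c"), a1 = rep(0.5, 3))
  expect_error(group_path_tests(degenerate), class = "membias_degenerate_error")
})

test_that("path-bias correlations separate true dependency from overestimation", {
  # population where the bias is tied to the value effect on actual memory
  # (via a shared driver) but not to the direct estimation path
  coh <- small_cohort(n = 12, seed = 75)
  paths <- path_coefficients(coh)
  coefs <- participant_coefficients(coh, min_trials = 5)
  res <- correlate_paths_with_bias(paths, coefs)
  expect_equal(res$pair, c("a1_vs_bias", "c1_vs_bias"))
  expect_true(all(abs(res$statistic) <= 1))
  # a bias vector equal to a1 correlates perfectly
  fake <- coefs
  fake$b0_h1 <- paths$a1
  res <- correlate_paths_with_bias(paths, fake)
  expect_equal(res$statistic[1], 1, tolerance = 1e-12)
  # constant bias is degenerate
  fake$b0_h1 <- rep(1, nrow(fake))
  expect_error(correlate_paths_with_bias(paths, fake),
               class = "membias_degenerate_error")
})
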