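test_that("a written bundle round-trips to an identical cohort", {
  coh <- small_cohort(n = 5, seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  sorted <- membias:::cohort_sort(coh)
  for (tab in c("ratings", "design", "recalls", "decisions", "estimates")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(sorted[[tab]]),
                 ignore_attr = TRUE)
  }
  # ground-truth parameters ride along
  expect_equal(as.data.frame(back$true_params), as.data.frame(coh$true_params),
               ignore_attr = TRUE)
})

test_that("round-tripping preserves the per-participant bias statistic", {
  coh <- small_cohort(n = 5, seed = 12)
  pre <- participant_coefficients(coh, min_trials = 5)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  post <- participant_coefficients(read_cohort(dir), min_trials = 5)
  expect_equal(post$b0_h1, pre$b0_h1, tolerance = 1e-12)
  expect_equal(post$b1_h2, pre$b1_h2, tolerance = 1e-12)
})

test_that("writing is deterministic byte for byte", {
  coh <- small_cohort(n = 3, seed = 13)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(coh, d1)
  write_cohort(coh, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("an empty cohort writes header-only files and reads back", {
  empty <- cohort(
    ratings = tibble::tibble(participant_id = character(), snack_id = character(),
                             rating = numeric(), adjusted = logical()),
    design = tibble::tibble(participant_id = character(), block = integer(),
                            snack_id = character(), location = integer()),
    recalls = tibble::tibble(participant_id = character(), block = integer(),
                             snack_id = character(), location = integer(),
                             correct = integer(), strength = numeric()),
    decisions = tibble::tibble(participant_id = character(), block = integer(),
                               trial = integer(), snack_a = character(),
                               snack_b = character(), choice = character()),
    estimates = tibble::tibble(participant_id = character(), snack_id = character(),
                               estimate = integer())
  )
  dir <- withr::local_tempdir()
  write_cohort(empty, dir)
  for (f in list.files(dir, pattern = "csv$")) {
    expect_length(readLines(file.path(dir, f)), 1L)
  }
  expect_equal(nrow(read_cohort(dir)$ratings), 0L)
})

test_that("row counts follow the design arithmetic", {
  cfg <- small_config()
  n <- 4L
  coh <- small_cohort(n = n, seed = 14)
  expect_equal(nrow(coh$recalls), n * cfg$n_blocks * cfg$set_size)
  expect_equal(nrow(coh$decisions), n * cfg$n_blocks * cfg$n_pairs)
  n_used <- cfg$n_blocks * cfg$set_size / cfg$occurrences
  expect_equal(nrow(coh$estimates), n * n_used)
})

test_that("invariant violations are rejected with the participant named", {
  coh <- small_cohort(n = 2, seed = 15)
  bad <- coh
  bad$estimates$estimate[1] <- 7L
  expect_error(validate_cohort(bad), class = "membias_validation_error",
               regexp = "0..6")
  bad <- coh
  bad$ratings$rating[3] <- 10.5
  expect_error(validate_cohort(bad), class = "membias_validation_error",
               regexp = "rating")
  bad <- coh
  bad$decisions$snack_b[1] <- bad$decisions$snack_a[1]
  expect_error(validate_cohort(bad), class = "membias_validation_error")
  bad <- coh
  bad$recalls <- bad$recalls[-1, ]
  expect_error(validate_cohort(bad), class = "membias_validation_error")
})

test_that("reading a bundle with a missing file is an I/O error", {
  coh <- small_cohort(n = 2, seed = 16)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  unlink(file.path(dir, "recalls.csv"))
  expect_error(read_cohort(dir), class = "membias_io_error", regexp = "recalls")
})
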