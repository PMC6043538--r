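test_that("the default design uses 24 snacks, each occurring exactly 6 times", {
  set.seed(21)
  d <- build_trial_sets(random_ratings(48))
  occ <- table(d$blocks$snack_id)
  expect_length(occ, 24L)
  expect_true(all(occ == 6L))
  expect_equal(nrow(d$blocks), 24L * 6L)
  expect_equal(nrow(d$pairs), 24L * 9L)
})

test_that("favorites are excluded and blocks mix all value tiers", {
  set.seed(22)
  ratings <- random_ratings(48)
  d <- build_trial_sets(ratings)
  favorites <- ratings$snack_id[order(-ratings$rating, ratings$snack_id)][1:6]
  expect_length(intersect(unique(d$blocks$snack_id), favorites), 0L)
  rep <- validate_design(d)
  expect_true(all(rep$pass[rep$constraint %in%
    c("occurrences", "set_size", "tier_mix", "location_diversity",
      "pairs_valid", "pairs_distinct")]))
})

test_that("a scaled geometry yields the implied occurrence bookkeeping", {
  set.seed(23)
  cfg <- design_config(n_blocks = 4L, set_size = 3L, occurrences = 2L,
                       n_pairs = 3L, n_excluded_favorites = 0L)
  d <- build_trial_sets(random_ratings(12), cfg)
  occ <- table(d$blocks$snack_id)
  expect_length(occ, 6L)
  expect_true(all(occ == 2L))
})

test_that("infeasible configurations are rejected", {
  expect_error(design_config(n_blocks = 5L, set_size = 3L, occurrences = 2L,
                             n_pairs = 3L),
               class = "membias_config_error")
  expect_error(design_config(n_pairs = 16L), class = "membias_config_error")
  set.seed(24)
  expect_error(build_trial_sets(random_ratings(20)),
               class = "membias_config_error", regexp = "at least")
})

test_that("pair schedules are balanced 3-regular for the default geometry", {
  set.seed(25)
  for (i in 1:20) {
    p <- schedule_decision_pairs(letters[1:6], 9L)
    expect_equal(nrow(p), 9L)
    deg <- table(c(p$snack_a, p$snack_b))
    expect_true(all(deg == 3L))
    key <- paste(pmin(p$snack_a, p$snack_b), pmax(p$snack_a, p$snack_b))
    expect_false(any(duplicated(key)))
  }
})

test_that("requesting all pairs returns the exhaustive set; too many errors", {
  set.seed(26)
  p <- schedule_decision_pairs(letters[1:6], 15L)
  key <- paste(pmin(p$snack_a, p$snack_b), pmax(p$snack_a, p$snack_b))
  expect_equal(sort(key), sort(apply(combn(letters[1:6], 2), 2,
                                     function(s) paste(s[1], s[2]))))
  expect_error(schedule_decision_pairs(letters[1:6], 16L),
               class = "membias_config_error")
})

test_that("unbalanced pair counts fall back to random sampling with a warning", {
  set.seed(27)
  expect_warning(p <- schedule_decision_pairs(letters[1:6], 8L),
                 regexp = "balanced")
  expect_equal(nrow(p), 8L)
})

test_that("validate_design reports constructed violations", {
  set.seed(28)
  d <- build_trial_sets(random_ratings(48))
  # force a consecutive repeat: put a block-3 snack into block 4
  broken <- d
  s3 <- broken$blocks$snack_id[broken$blocks$block == 3][1]
  out4 <- setdiff(broken$blocks$snack_id[broken$blocks$block == 4], s3)[1]
  i <- which(broken$blocks$block == 4 & broken$blocks$snack_id == out4)[1]
  broken$blocks$snack_id[i] <- s3
  rep <- validate_design(broken)
  expect_gte(rep$count[rep$constraint == "consecutive_repeats"], 1L)
  # the swap also breaks the occurrence count, naming the snack
  occ_row <- rep[rep$constraint == "occurrences", ]
  expect_false(occ_row$pass)
  expect_match(occ_row$detail, out4)
})

test_that("identical ratings, config and seed give identical designs", {
  ratings <- random_ratings(48)
  d1 <- build_trial_sets(ratings, seed = 99L)
  d2 <- build_trial_sets(ratings, seed = 99L)
  expect_identical(d1$blocks, d2$blocks)
  expect_identical(d1$pairs, d2$pairs)
})
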