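#' Population-level parameters of the synthetic cohort
#'
#' Each behavioral parameter is drawn per participant from a normal
#' distribution with the given `c(mean, sd)`; the memory-bias intercept
#' `b0_choice` and the direct value weight on memory estimation
#' `gamma1_est` are drawn jointly bivariate-normal with correlation
#' `rho_bias_belief`, which is what ties the bias to the belief in
#' value-dependent memory at the population level.
#'
#' Defaults are chosen so that simulated cohorts land in a realistic regime
#' for this task: recall rate near 50% (`alpha_mem` centered at 0), a
#' clearly positive memory bias (group d around 0.7-0.8), and value effects
#' on actual recall performance weaker than those on self-estimated memory.
#' They are plausibility choices for testing, not estimates fitted to any
#' data set.
#'
#' @param alpha_mem Recall log-odds baseline.
#' @param beta1_mem,beta2_mem Linear and quadratic standardized-value
#'   effects on recall log-odds.
#' @param b0_choice Memory-bias intercept in one-remembered decisions.
#' @param b1_choice Value slope of the remembered option in one-remembered
#'   decisions.
#' @param b_val Value-difference slope in both-remembered decisions.
#' @param gamma0_est,gamma_perf,gamma1_est,gamma2_est,sigma_est Memory
#'   estimation: intercept, weight of the actual recall count, direct linear
#'   and quadratic value weights, and noise SD (0-6 estimate scale).
#' @param lambda_corr,lambda1,sigma_str Strength ratings: weight of recall
#'   correctness, of value, and noise SD (0-1 scale).
#' @param p_miss Probability that a decision trial is missed (5 s deadline).
#' @param rho_bias_belief Population correlation between `b0_choice` and
#'   `gamma1_est`.
#' @param n_snacks Number of rated snacks per participant.
#' @param rating_range Range of the uniform rating distribution.
#' @return A list of class `membias_population`.
#' @export
population_params <- function(alpha_mem = c(0, 0.5),
                              beta1_mem = c(0.2, 0.35),
                              beta2_mem = c(0.15, 0.3),
                              b0_choice = c(0.5, 0.6),
                              b1_choice = c(1.0, 0.5),
                              b_val = c(1.5, 0.5),
                              gamma0_est = c(1.5, 0.3),
                              gamma_perf = c(0.5, 0.15),
                              gamma1_est = c(0.3, 0.25),
                              gamma2_est = c(0.15, 0.2),
                              sigma_est = c(0.5, 0.1),
                              lambda_corr = c(0.5, 0.1),
                              lambda1 = c(0.1, 0.05),
                              sigma_str = c(0.15, 0.05),
                              p_miss = c(0.02, 0.01),
                              rho_bias_belief = 0.4,
                              n_snacks = 48L,
                              rating_range = c(0, 10)) {
  pars <- list(
    alpha_mem = alpha_mem, beta1_mem = beta1_mem, beta2_mem = beta2_mem,
    b0_choice = b0_choice, b1_choice = b1_choice, b_val = b_val,
    gamma0_est = gamma0_est, gamma_perf = gamma_perf,
    gamma1_est = gamma1_est, gamma2_est = gamma2_est, sigma_est = sigma_est,
    lambda_corr = lambda_corr, lambda1 = lambda1, sigma_str = sigma_str,
    p_miss = p_miss
  )
  for (nm in names(pars)) {
    p <- pars[[nm]]
    if (length(p) != 2L || !all(is.finite(p)) || p[2] < 0) {
      abort(paste0(nm, " must be c(mean, sd) with sd >= 0"),
            class = "membias_config_error")
    }
  }
  if (!is.finite(rho_bias_belief) || abs(rho_bias_belief) > 1) {
    abort("rho_bias_belief must lie in [-1, 1]", class = "membias_config_error")
  }
  structure(
    c(pars, list(rho_bias_belief = rho_bias_belief,
                 n_snacks = as.integer(n_snacks),
                 rating_range = rating_range)),
    class = "membias_population"
  )
}

param_names <- c("alpha_mem", "beta1_mem", "beta2_mem", "b0_choice", "b1_choice",
                 "b_val", "gamma0_est", "gamma_perf", "gamma1_est", "gamma2_est",
                 "sigma_est", "lambda_corr", "lambda1", "sigma_str", "p_miss")

#' Draw one participant's behavioral parameters
#'
#' All parameters are independent normal draws from their population
#' distribution except `(b0_choice, gamma1_est)`, which are bivariate
#' normal with correlation `rho_bias_belief`. Scale parameters are
#' truncated to their valid ranges (`sigma_* >= 0`, `p_miss` in
#' `[0, 0.99]`, `lambda_corr` in `[0, 1]`).
#'
#' @param pop A [population_params()] object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Named list of parameter values.
#' @export
draw_participant_params <- function(pop, seed = NULL) {
  stopifnot(inherits(pop, "membias_population"))
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  # fixed draw order keeps cohorts reproducible under a single seed
  z_bias <- rnorm(2L)
  rho <- pop$rho_bias_belief
  out$b0_choice <- pop$b0_choice[1] + pop$b0_choice[2] * z_bias[1]
  out$gamma1_est <- pop$gamma1_est[1] +
    pop$gamma1_est[2] * (rho * z_bias[1] + sqrt(1 - rho^2) * z_bias[2])
  for (nm in setdiff(param_names, c("b0_choice", "gamma1_est"))) {
    out[[nm]] <- rnorm(1L, pop[[nm]][1], pop[[nm]][2])
  }
  out$sigma_est <- max(out$sigma_est, 0)
  out$sigma_str <- max(out$sigma_str, 0)
  out$lambda_corr <- min(max(out$lambda_corr, 0), 1)
  out$p_miss <- min(max(out$p_miss, 0), 0.99)
  out[param_names]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate one participant's task record
#'
#' Generates cued-recall outcomes, paired decisions, strength ratings and
#' memory estimates for a given block design. Per block, recall of a snack
#' with standardized value `z` and restandardized squared value `q` is
#' Bernoulli with log-odds `alpha_mem + beta1_mem*z + beta2_mem*q`.
#' Decisions: with both options remembered the higher-valued option is
#' favored via log-odds `b_val*(z_a - z_b)`; with exactly one remembered the
#' remembered option is chosen with log-odds `b0_choice + b1_choice*z_rem`
#' (the intercept is the generative memory bias); with both forgotten the
#' choice is a fair coin; every decision is independently missed with
#' probability `p_miss`. The memory estimate of a snack recalled `k` times
#' is `gamma0_est + gamma_perf*k + gamma1_est*z + gamma2_est*q` plus
#' Gaussian noise, rounded and clipped to 0-6 — estimation thus tracks both
#' actual recall and value.
#'
#' @param params Parameter list from [draw_participant_params()].
#' @param ratings Tibble with `snack_id`, `rating` for this participant.
#' @param design A `membias_design` built from the same ratings.
#' @param participant_id Identifier stamped into the output tables.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List of class `membias_participant` with tibbles `ratings`,
#'   `design`, `recalls`, `decisions`, `estimates`.
#' @export
simulate_participant <- function(params, ratings, design,
                                 participant_id = "p001", seed = NULL) {
  stopifnot(inherits(design, "membias_design"))
  if (!is.null(seed)) set.seed(seed)
  used <- design$used_snacks$snack_id
  r_used <- ratings$rating[match(used, ratings$snack_id)]
  if (anyNA(r_used)) {
    abort("design references snacks absent from the ratings",
          class = "membias_validation_error")
  }
  z <- standardize_values(r_used)
  q <- quadratic_term(z)

  blocks <- design$blocks
  bi <- match(blocks$snack_id, used)
  zi <- z[bi]
  qi <- q[bi]
  n_rec <- nrow(blocks)
  p_rec <- plogis(params$alpha_mem + params$beta1_mem * zi + params$beta2_mem * qi)
  correct <- rbinom(n_rec, 1L, p_rec)
  strength <- clip01(params$lambda_corr * correct + params$lambda1 * zi +
                       rnorm(n_rec, 0, params$sigma_str) +
                       0.5 * (1 - params$lambda_corr))
  recalls <- tibble(
    participant_id = participant_id,
    block = blocks$block, snack_id = blocks$snack_id,
    location = blocks$location,
    correct = as.integer(correct), strength = strength
  )

  pairs <- design$pairs
  rec_key <- paste(blocks$block, blocks$snack_id)
  ia <- match(paste(pairs$block, pairs$snack_a), rec_key)
  ib <- match(paste(pairs$block, pairs$snack_b), rec_key)
  rem_a <- correct[ia] == 1L
  rem_b <- correct[ib] == 1L
  z_a <- zi[ia]
  z_b <- zi[ib]
  p_choose_a <- ifelse(
    rem_a & rem_b, plogis(params$b_val * (z_a - z_b)),
    ifelse(rem_a & !rem_b, plogis(params$b0_choice + params$b1_choice * z_a),
           ifelse(!rem_a & rem_b,
                  1 - plogis(params$b0_choice + params$b1_choice * z_b), 0.5))
  )
  n_dec <- nrow(pairs)
  choice <- ifelse(runif(n_dec) < p_choose_a, "a", "b")
  choice[runif(n_dec) < params$p_miss] <- "missed"
  decisions <- tibble(
    participant_id = participant_id,
    block = pairs$block, trial = pairs$trial,
    snack_a = pairs$snack_a, snack_b = pairs$snack_b, choice = choice
  )

  k <- as.vector(rowsum(correct, factor(blocks$snack_id, levels = used)))
  latent <- params$gamma0_est + params$gamma_perf * k +
    params$gamma1_est * z + params$gamma2_est * q +
    rnorm(length(used), 0, params$sigma_est)
  estimates <- tibble(
    participant_id = participant_id,
    snack_id = used,
    estimate = as.integer(pmin(pmax(round(latent), 0), 6))
  )

  ratings_out <- tibble(
    participant_id = participant_id,
    snack_id = ratings$snack_id, rating = ratings$rating,
    adjusted = if ("adjusted" %in% names(ratings)) ratings$adjusted else FALSE
  )
  design_out <- tibble(
    participant_id = participant_id,
    block = blocks$block, snack_id = blocks$snack_id, location = blocks$location
  )
  structure(
    list(ratings = ratings_out, design = design_out, recalls = recalls,
         decisions = decisions, estimates = estimates),
    class = "membias_participant"
  )
}

#' Simulate a full cohort
#'
#' Draws `n` participants, each with fresh uniform snack ratings, a fresh
#' constrained block design via [build_trial_sets()], and fresh behavioral
#' parameters via [draw_participant_params()]. Deterministic given
#' `(pop, n, seed, config)`.
#'
#' @param pop A [population_params()] object.
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed for the whole cohort.
#' @param config A [design_config()].
#' @param validate Validate the assembled cohort (default `TRUE`).
#' @return A `membias_cohort` with an extra element `true_params`: a tibble
#'   of each participant's generative parameters, for recovery studies.
#' @export
simulate_cohort <- function(pop = population_params(), n, seed = NULL,
                            config = design_config(), validate = TRUE) {
  stopifnot(inherits(pop, "membias_population"))
  if (n < 1) abort("n must be >= 1", class = "membias_config_error")
  if (!is.null(seed)) set.seed(seed)
  width <- max(3L, nchar(as.character(n)))
  snack_ids <- sprintf("snack_%02d", seq_len(pop$n_snacks))
  recs <- vector("list", n)
  par_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("p%0*d", width, i)
    ratings <- tibble(
      snack_id = snack_ids,
      rating = runif(pop$n_snacks, pop$rating_range[1], pop$rating_range[2]),
      adjusted = FALSE
    )
    params <- draw_participant_params(pop)
    design <- build_trial_sets(ratings, config)
    recs[[i]] <- simulate_participant(params, ratings, design, participant_id = pid)
    par_rows[[i]] <- tibble(participant_id = pid, !!!params)
  }
  out <- cohort(
    ratings = dplyr::bind_rows(lapply(recs, `[[`, "ratings")),
    design = dplyr::bind_rows(lapply(recs, `[[`, "design")),
    recalls = dplyr::bind_rows(lapply(recs, `[[`, "recalls")),
    decisions = dplyr::bind_rows(lapply(recs, `[[`, "decisions")),
    estimates = dplyr::bind_rows(lapply(recs, `[[`, "estimates")),
    provenance = paste0("simulated: n = ", n,
                        if (!is.null(seed)) paste0(", seed = ", seed) else ""),
    validate = validate
  )
  out$true_params <- dplyr::bind_rows(par_rows)
  out
}
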