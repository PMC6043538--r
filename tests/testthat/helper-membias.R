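# Scaled-down task geometry for fast unit tests: 8 blocks of 4 snacks,
# 8 used snacks occurring 4 times each, 4 decision pairs per block.
small_config <- function() {
  design_config(n_blocks = 8L, set_size = 4L, occurrences = 4L, n_pairs = 4L,
                n_excluded_favorites = 2L, value_tiers = 2L)
}

small_pop <- function(...) {
  population_params(n_snacks = 16L, ...)
}

small_cohort <- function(n = 5L, seed = 1L, pop = small_pop()) {
  simulate_cohort(pop, n = n, seed = seed, config = small_config())
}

random_ratings <- function(n_snacks = 48L) {
  tibble::tibble(snack_id = sprintf("snack_%02d", seq_len(n_snacks)),
                 rating = runif(n_snacks, 0, 10), adjusted = FALSE)
}

# independent ML oracle: direct likelihood maximization by Nelder-Mead,
# polished by a restart from its own solution
logistic_oracle <- function(X, y, start = NULL) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta)))
  }
  if (ncol(X) == 1L) {
    return(optimize(function(b) nll(b), c(-30, 30), tol = 1e-10)$minimum)
  }
  b <- if (is.null(start)) rep(0, ncol(X)) else start
  for (i in 1:3) {
    b <- optim(b, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))$par
  }
  b
}
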