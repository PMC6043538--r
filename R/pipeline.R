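#' Analysis configuration
#'
#' @param min_one_remembered Minimum usable one-remembered trials for the
#'   per-participant bias regression.
#' @param exclusions Optional [exclusion_criteria()]; when supplied the
#'   analysis runs on the restricted sample and labels its rows so.
#' @param include_strength_paths Also fit the strength-mediator path model.
#' @param df_convention Degrees-of-freedom convention for [summed_lrt()].
#' @param lilliefors Use the Lilliefors correction in normality checks.
#' @return A list of class `membias_analysis_config`.
#' @export
analysis_config <- function(min_one_remembered = 10L, exclusions = NULL,
                            include_strength_paths = FALSE,
                            df_convention = c("n", "n_minus_1"),
                            lilliefors = FALSE) {
  structure(
    list(min_one_remembered = as.integer(min_one_remembered),
         exclusions = exclusions,
         include_strength_paths = include_strength_paths,
         df_convention = match.arg(df_convention),
         lilliefors = lilliefors),
    class = "membias_analysis_config"
  )
}

t_row <- function(analysis, values, sidedness, sample) {
  res <- one_sample_t(values, mu0 = 0, sidedness = sidedness)
  tibble(analysis = analysis, statistic_type = "t", statistic = res$statistic,
         df = res$df, p = res$p, effect_size = res$effect_size, n = res$n,
         sidedness = sidedness, sample = sample)
}

r_row <- function(analysis, x, y, sidedness, sample) {
  res <- pearson_r(x, y, sidedness = sidedness)
  tibble(analysis = analysis, statistic_type = "r", statistic = res$statistic,
         df = res$df, p = res$p, effect_size = res$statistic, n = res$n,
         sidedness = sidedness, sample = sample)
}

chisq_row <- function(analysis, restricted, full, ids, df_convention, sample) {
  res <- summed_lrt(restricted, full, participant_id = ids,
                    df_convention = df_convention, label = analysis)
  tibble(analysis = analysis, statistic_type = "chisq", statistic = res$chi_sq,
         df = as.numeric(res$df), p = res$p, effect_size = NA_real_,
         n = res$n_participants, sidedness = "upper", sample = sample)
}

#' Run the complete analysis battery on a cohort
#'
#' Executes, in order: optional exclusions, per-participant statistics
#' ([participant_coefficients()]), the three hypothesis-driven tests
#' (memory bias, value-dependent memory estimation, their correlation; all
#' one-sided), the exploratory quadratic and performance regressions, the
#' four summed-deviance likelihood-ratio model comparisons, the
#' performance-controlled estimation regression, the forgotten-value test,
#' the corrected memory bias, the per-participant path analysis with group
#' tests, and the correlations of path coefficients with the bias
#' (exploratory tests two-sided). Deterministic given cohort and config.
#'
#' @param x A `membias_cohort`.
#' @param config An [analysis_config()].
#' @return An object of class `membias_results`: list with `table` (one row
#'   per analysis), `coefs`, `paths`, `path_tests`, `path_bias_correlations`,
#'   `normality`, `exclusion_log`, `sample`, `config`.
#' @export
run_full_analysis <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "membias_cohort"),
            inherits(config, "membias_analysis_config"))
  exclusion_log <- NULL
  sample <- "full"
  if (!is.null(config$exclusions)) {
    excl <- apply_exclusions(x, config$exclusions)
    x <- excl$cohort
    exclusion_log <- excl$log
    sample <- "restricted"
  }
  coefs <- participant_coefficients(x, min_trials = config$min_one_remembered)
  paths <- path_coefficients(x, include_strength = config$include_strength_paths)

  normality <- dplyr::bind_cols(
    tibble(coefficient = c("b0_h1", "b1_h2")),
    dplyr::bind_rows(
      ks_normality(coefs$b0_h1, lilliefors = config$lilliefors),
      ks_normality(coefs$b1_h2, lilliefors = config$lilliefors)
    )
  )

  ok_pair <- is.finite(coefs$b0_h1) & is.finite(coefs$b1_h2)
  rows <- list(
    t_row("H1: memory bias (b0_h1)", coefs$b0_h1, "greater", sample),
    t_row("H2: value-dependent memory estimation (b1_h2)", coefs$b1_h2,
          "greater", sample),
    r_row("H3: correlation memory bias x value-dependent estimation",
          coefs$b0_h1[ok_pair], coefs$b1_h2[ok_pair], "greater", sample),
    t_row("Quadratic effect of value on memory estimation",
          coefs$b_h2_quadratic, "two.sided", sample),
    t_row("Linear effect of value on memory performance",
          coefs$perf_linear, "two.sided", sample),
    t_row("Quadratic effect of value on memory performance",
          coefs$perf_quadratic, "two.sided", sample),
    chisq_row("LRT estimation: linear-and-quadratic > linear-only",
              coefs$est_dev_lin, coefs$est_dev_full, coefs$participant_id,
              config$df_convention, sample),
    chisq_row("LRT estimation: linear-and-quadratic > quadratic-only",
              coefs$est_dev_quad, coefs$est_dev_full, coefs$participant_id,
              config$df_convention, sample),
    chisq_row("LRT performance: linear-and-quadratic > linear-only",
              coefs$perf_dev_lin, coefs$perf_dev_full, coefs$participant_id,
              config$df_convention, sample),
    chisq_row("LRT performance: linear-and-quadratic > quadratic-only",
              coefs$perf_dev_quad, coefs$perf_dev_full, coefs$participant_id,
              config$df_convention, sample),
    t_row("Linear effect of memory performance on memory estimation",
          coefs$est_on_perf, "two.sided", sample),
    t_row("Linear effect of value on estimation controlling for performance",
          coefs$est_on_value_ctrl, "two.sided", sample),
    t_row("Standardized value of forgotten options",
          coefs$mean_forgotten_z, "two.sided", sample),
    t_row("Corrected memory bias", coefs$b0_corrected, "two.sided", sample)
  )
  path_tests <- group_path_tests(paths)
  rows <- c(rows, list(
    dplyr::bind_rows(lapply(seq_len(nrow(path_tests)), function(i) {
      tibble(analysis = paste0("Path: ", path_tests$coefficient[i]),
             statistic_type = "t", statistic = path_tests$statistic[i],
             df = path_tests$df[i], p = path_tests$p[i],
             effect_size = path_tests$effect_size[i], n = path_tests$n[i],
             sidedness = path_tests$sidedness[i], sample = sample)
    }))
  ))
  path_bias <- correlate_paths_with_bias(paths, coefs)
  rows <- c(rows, list(
    tibble(analysis = c("Correlation: value-on-performance path x memory bias",
                        "Correlation: value-on-estimation path x memory bias"),
           statistic_type = "r", statistic = path_bias$statistic,
           df = path_bias$df, p = path_bias$p, effect_size = path_bias$statistic,
           n = path_bias$n, sidedness = path_bias$sidedness, sample = sample)
  ))

  structure(
    list(table = dplyr::bind_rows(rows), coefs = coefs, paths = paths,
         path_tests = path_tests, path_bias_correlations = path_bias,
         normality = normality, exclusion_log = exclusion_log,
         sample = sample, config = config),
    class = "membias_results"
  )
}

#' @export
print.membias_results <- function(x, ...) {
  cat("<membias_results> (", x$sample, " sample, n = ",
      nrow(x$coefs), " participants)\n\n", sep = "")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    st <- switch(tab$statistic_type[i],
                 t = sprintf("t(%g) = %.2f", tab$df[i], tab$statistic[i]),
                 r = sprintf("r(%g) = %.2f", tab$df[i], tab$statistic[i]),
                 chisq = sprintf("chi2(%g) = %.1f", tab$df[i], tab$statistic[i]))
    es <- if (tab$statistic_type[i] == "t") sprintf(", d = %.2f", tab$effect_size[i]) else ""
    cat(sprintf("  %-62s %s, p = %.3g%s\n",
                substr(tab$analysis[i], 1, 62), st, tab$p[i], es))
  }
  invisible(x)
}

#' @method tidy membias_results
#' @export
tidy.membias_results <- function(x, ...) x$table

#' @method glance membias_results
#' @export
glance.membias_results <- function(x, ...) {
  g <- function(lbl) x$table[startsWith(x$table$analysis, lbl), ]
  tibble(
    n_participants = nrow(x$coefs),
    sample = x$sample,
    h1_t = g("H1")$statistic, h1_d = g("H1")$effect_size, h1_p = g("H1")$p,
    h2_t = g("H2")$statistic, h2_d = g("H2")$effect_size, h2_p = g("H2")$p,
    h3_r = g("H3")$statistic, h3_p = g("H3")$p
  )
}

# the two hypothesis-driven per-participant statistics, computed cheaply
h1_h2_stats <- function(x, min_trials = 10L) {
  recs <- participant_records(x)
  b0 <- b1h2 <- rep(NA_real_, length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    vt <- tryCatch(value_terms(rec), membias_degenerate_error = function(e) NULL)
    if (is.null(vt)) next
    cls <- classify_decision_trials(rec$decisions, rec$recalls)
    one <- cls[cls$trial_type == "one_remembered", , drop = FALSE]
    if (nrow(one) >= min_trials) {
      chose_rem <- as.numeric((one$choice == "a" & one$rem_a) |
                                (one$choice == "b" & one$rem_b))
      z_rem <- ifelse(one$rem_a, vt$z[one$snack_a], vt$z[one$snack_b])
      fit <- safe_fit(fit_logistic_mle(cbind(1, z_rem), chose_rem))
      if (!is.null(fit) && !fit$separation) b0[i] <- fit$coefficients[1]
    }
    est <- rec$estimates$estimate[match(vt$snack_id, rec$estimates$snack_id)]
    f <- safe_fit(fit_linear_ml(cbind("(Intercept)" = 1, z = unname(vt$z)), est))
    b1h2[i] <- coef_or_na(f, "z")
  }
  tibble(participant_id = names(recs), b0_h1 = b0, b1_h2 = b1h2)
}

#' Parameter-recovery study
#'
#' Simulates `n_cohorts` cohorts from a known population, runs the
#' per-participant analyses, and compares the cohort-mean estimates against
#' the generative truth: `b0_choice` against the mean memory bias,
#' `beta1_mem`/`beta2_mem` against the performance regression coefficients,
#' `gamma1_est` against the performance-controlled estimation coefficient
#' (whose estimand it is; the marginal H2 slope additionally absorbs the
#' mediated effect of value through actual recall), and `rho_bias_belief`
#' against the H3 correlation (attenuated by estimation noise; the
#' attenuation is reported, not assumed away).
#'
#' @param pop A [population_params()] object.
#' @param n_participants Participants per cohort.
#' @param n_cohorts Number of simulated cohorts.
#' @param seed Optional integer seed.
#' @param config A [design_config()].
#' @return Tibble: `parameter`, `truth`, `mean_estimate`, `bias`, `rmse`
#'   (of the cohort-level means), `n_cohorts`.
#' @export
parameter_recovery <- function(pop = population_params(), n_participants = 90L,
                               n_cohorts = 100L, seed = NULL,
                               config = design_config()) {
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_cohorts, 5,
                dimnames = list(NULL, c("b0_choice", "beta1_mem", "beta2_mem",
                                        "gamma1_est", "rho_bias_belief")))
  for (cc in seq_len(n_cohorts)) {
    coh <- simulate_cohort(pop, n_participants, config = config, validate = FALSE)
    coefs <- participant_coefficients(coh)
    est[cc, "b0_choice"] <- mean(coefs$b0_h1, na.rm = TRUE)
    est[cc, "beta1_mem"] <- mean(coefs$perf_linear, na.rm = TRUE)
    est[cc, "beta2_mem"] <- mean(coefs$perf_quadratic, na.rm = TRUE)
    est[cc, "gamma1_est"] <- mean(coefs$est_on_value_ctrl, na.rm = TRUE)
    ok <- is.finite(coefs$b0_h1) & is.finite(coefs$b1_h2)
    est[cc, "rho_bias_belief"] <- cor(coefs$b0_h1[ok], coefs$b1_h2[ok])
  }
  truth <- c(pop$b0_choice[1], pop$beta1_mem[1], pop$beta2_mem[1],
             pop$gamma1_est[1], pop$rho_bias_belief)
  means <- colMeans(est)
  tibble(
    parameter = colnames(est), truth = truth, mean_estimate = unname(means),
    bias = unname(means - truth),
    rmse = vapply(seq_len(5), function(j) sqrt(mean((est[, j] - truth[j])^2)),
                  numeric(1)),
    n_cohorts = n_cohorts
  )
}

#' Type-I error of the hypothesis-driven tests
#'
#' Simulates cohorts from a null population (the tested effect's population
#' mean set to 0) and reports how often each one-sided hypothesis-driven
#' test rejects at `alpha`: H1 (memory bias t-test), H2 (estimation-slope
#' t-test), H3 (bias-belief correlation).
#'
#' @param null_pop A [population_params()] with the relevant means at 0.
#' @param n_participants Participants per cohort.
#' @param n_cohorts Number of simulated cohorts.
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @param config A [design_config()].
#' @return Tibble: `test`, `rejections`, `n_cohorts`, `rate`, `alpha`.
#' @export
type_i_error <- function(null_pop, n_participants = 30L, n_cohorts = 500L,
                         alpha = 0.05, seed = NULL, config = design_config()) {
  if (!is.null(seed)) set.seed(seed)
  rej <- c(H1 = 0L, H2 = 0L, H3 = 0L)
  for (cc in seq_len(n_cohorts)) {
    coh <- simulate_cohort(null_pop, n_participants, config = config,
                           validate = FALSE)
    st <- h1_h2_stats(coh)
    p1 <- one_sample_t(st$b0_h1, sidedness = "greater")$p
    p2 <- one_sample_t(st$b1_h2, sidedness = "greater")$p
    ok <- is.finite(st$b0_h1) & is.finite(st$b1_h2)
    p3 <- pearson_r(st$b0_h1[ok], st$b1_h2[ok], sidedness = "greater")$p
    rej <- rej + as.integer(c(p1, p2, p3) < alpha)
  }
  tibble(test = names(rej), rejections = unname(rej), n_cohorts = n_cohorts,
         rate = unname(rej) / n_cohorts, alpha = alpha)
}
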