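#' Standardize snack values within a participant
#'
#' @param x Numeric ratings.
#' @return `(x - mean(x)) / sd(x)` with the sample SD (denominator n-1).
#'   Errors on fewer than 2 distinct values.
#' @export
standardize_values <- function(x) {
  if (length(x) < 2L || !all(is.finite(x))) {
    abort("need at least two finite ratings to standardize",
          class = "membias_degenerate_error")
  }
  s <- sd(x)
  if (s == 0) {
    abort("ratings have zero variance; participant cannot be standardized",
          class = "membias_degenerate_error")
  }
  (x - mean(x)) / s
}

#' Quadratic value term: squared then restandardized
#'
#' The quadratic regressor is the square of the standardized value,
#' standardized again, so both regressors enter the models on the same
#' (mean 0, SD 1) scale.
#'
#' @param z Standardized values from [standardize_values()].
#' @return Standardized `z^2`.
#' @export
quadratic_term <- function(z) {
  z2 <- z^2
  if (length(z2) < 2L || sd(z2) == 0) {
    abort("squared values are constant; quadratic term undefined",
          class = "membias_degenerate_error")
  }
  standardize_values(z2)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with explicit convergence and
#' separation semantics: Newton/IRLS steps with step-halving, declared
#' converged when the maximum absolute score drops below `tol_score` or the
#' relative deviance change below `tol_dev`. The separation flag is set when
#' fitted probabilities pin to 0/1 (within 1e-6) together with unbounded
#' coefficient growth; callers treat separated fits as missing statistics.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary outcomes (0/1).
#' @param max_iter Maximum IRLS iterations.
#' @param tol_score Convergence threshold on `max |X'(y - mu)|`.
#' @param tol_dev Convergence threshold on the relative deviance change.
#' @return A list of class `membias_glm` with elements `coefficients`,
#'   `log_likelihood`, `deviance` (-2 log-likelihood), `n_obs`, `converged`,
#'   `separation`, `family = "binomial"`.
#' @export
fit_logistic_mle <- function(X, y, max_iter = 100L, tol_score = 1e-8,
                             tol_dev = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("X and y sizes differ", class = "membias_fit_error")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1", class = "membias_fit_error")
  if (qr(X)$rank < p) {
    abort("design matrix is rank-deficient (collinear columns)",
          class = "membias_fit_error")
  }
  beta <- numeric(p)
  eta <- numeric(n)
  mu <- rep(0.5, n)
  dev <- binomial_deviance(y, mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(solve(crossprod(X * sqrt(w)), score),
                      error = function(e) NULL)
    if (is.null(delta)) {
      abort("IRLS weighted normal equations are singular",
            class = "membias_fit_error")
    }
    step <- 1
    repeat {
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(X %*% beta_new)
      mu_new <- plogis(eta_new)
      dev_new <- binomial_deviance(y, mu_new)
      if (is.finite(dev_new) && (dev_new <= dev + 1e-8 || step < 1 / 64)) break
      step <- step / 2
    }
    beta <- beta_new
    mu <- mu_new
    rel_dev <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    dev <- dev_new
    if (max(abs(crossprod(X, y - mu))) < tol_score || rel_dev < tol_dev) {
      converged <- TRUE
      break
    }
  }
  separation <- any(mu < 1e-6 | mu > 1 - 1e-6) && max(abs(beta)) > 10
  if (!converged && !separation) {
    abort(paste0("logistic regression did not converge in ", max_iter, " iterations"),
          class = "membias_fit_error")
  }
  structure(
    list(coefficients = setNames(drop(beta), colnames(X)),
         log_likelihood = -dev / 2, deviance = dev, n_obs = n,
         converged = converged, separation = separation, family = "binomial"),
    class = "membias_glm"
  )
}

#' Linear regression with a maximum-likelihood deviance
#'
#' Ordinary least squares (via the QR decomposition in [stats::lm.fit])
#' whose reported deviance is -2 times the Gaussian log-likelihood at the
#' ML variance estimate (RSS/n), so that nested linear models can be
#' compared by the same summed-deviance likelihood-ratio machinery as the
#' logistic models.
#'
#' @inheritParams fit_logistic_mle
#' @param y Numeric outcomes.
#' @return A `membias_glm` with `family = "gaussian"` (extra element `rss`).
#' @export
fit_linear_ml <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank-deficient (collinear columns)",
          class = "membias_fit_error")
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, .Machine$double.xmin)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(
    list(coefficients = setNames(drop(fit$coefficients), colnames(X)),
         log_likelihood = ll, deviance = -2 * ll, n_obs = n,
         converged = TRUE, separation = FALSE, family = "gaussian", rss = rss),
    class = "membias_glm"
  )
}

#' @export
print.membias_glm <- function(x, ...) {
  cat("<membias_glm> ", x$family, ", n = ", x$n_obs,
      ", deviance = ", format(x$deviance, digits = 6), "\n", sep = "")
  print(x$coefficients)
  if (x$separation) cat("  (separation detected)\n")
  invisible(x)
}

#' @method tidy membias_glm
#' @export
tidy.membias_glm <- function(x, ...) {
  tibble(term = names(x$coefficients) %||% paste0("x", seq_along(x$coefficients)),
         estimate = unname(x$coefficients))
}

#' @method glance membias_glm
#' @export
glance.membias_glm <- function(x, ...) {
  tibble(deviance = x$deviance, log_likelihood = x$log_likelihood,
         n_obs = x$n_obs, converged = x$converged, separation = x$separation,
         family = x$family)
}

#' Split a cohort into per-participant records
#'
#' @param x A `membias_cohort`.
#' @return Named list of `membias_participant` records (each a list of the
#'   participant's `ratings`, `design`, `recalls`, `decisions`, `estimates`).
#' @export
participant_records <- function(x) {
  stopifnot(inherits(x, "membias_cohort"))
  ids <- participants(x)
  split_tab <- function(tab) split(tab, factor(tab$participant_id, levels = ids))
  parts <- lapply(cohort_tables, function(tab) split_tab(x[[tab]]))
  names(parts) <- cohort_tables
  out <- lapply(ids, function(id) {
    structure(lapply(parts, `[[`, id), class = "membias_participant")
  })
  names(out) <- ids
  out
}

# standardized value (z) and quadratic term (q) per used snack
value_terms <- function(record) {
  used <- unique(record$design$snack_id)
  r <- record$ratings$rating[match(used, record$ratings$snack_id)]
  if (anyNA(r)) {
    abort("design references snacks absent from the ratings",
          class = "membias_validation_error")
  }
  z <- standardize_values(r)
  list(snack_id = used, z = setNames(z, used),
       q = setNames(quadratic_term(z), used))
}

#' Classify decision trials by the recall status of their options
#'
#' A trial is `missed` when no response was given (precedence over recall
#' status); otherwise `both_remembered`, `one_remembered` or
#' `both_forgotten` according to that block's cued-recall correctness of
#' the two options.
#'
#' @param decisions Decision tibble (may span multiple participants).
#' @param recalls Matching recall tibble.
#' @return `decisions` with logical columns `rem_a`, `rem_b` and a
#'   `trial_type` column.
#' @export
classify_decision_trials <- function(decisions, recalls) {
  key <- paste(recalls$participant_id, recalls$block, recalls$snack_id)
  ia <- match(paste(decisions$participant_id, decisions$block, decisions$snack_a), key)
  ib <- match(paste(decisions$participant_id, decisions$block, decisions$snack_b), key)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- which(is.na(ia) | is.na(ib))[1]
    abort(paste0("decision references a snack with no recall outcome (participant ",
                 decisions$participant_id[bad], ", block ", decisions$block[bad], ")"),
          class = "membias_validation_error")
  }
  rem_a <- recalls$correct[ia] == 1L
  rem_b <- recalls$correct[ib] == 1L
  decisions$rem_a <- rem_a
  decisions$rem_b <- rem_b
  decisions$trial_type <- dplyr::case_when(
    decisions$choice == "missed" ~ "missed",
    rem_a & rem_b ~ "both_remembered",
    !rem_a & !rem_b ~ "both_forgotten",
    TRUE ~ "one_remembered"
  )
  decisions
}

missing_bias <- function(reason, n_trials = NA_integer_) {
  tibble(b0 = NA_real_, b1 = NA_real_, mean_forgotten_z = NA_real_,
         n_trials = n_trials, converged = FALSE, separation = FALSE,
         reason = reason)
}

#' The per-participant memory bias
#'
#' For the trials in which exactly one option was remembered (per the
#' block's cued recall) and a choice was made, fits the logistic regression
#' of choosing the remembered option on that option's standardized value.
#' The intercept `b0` is the memory bias: a positive value means the
#' remembered option is preferred even at average value. With
#' `corrected = TRUE` the regressor is shifted by the participant's mean
#' standardized value over all forgotten snack-block instances
#' (`mean_forgotten_z`), so the intercept measures the preference beyond
#' what forgotten options being objectively worse would justify.
#'
#' @param record A `membias_participant` (see [participant_records()]).
#' @param corrected Shift the regressor by `mean_forgotten_z`.
#' @param min_trials Minimum usable one-remembered trials; below it the
#'   statistic is returned missing with a reason.
#' @return One-row tibble: `b0`, `b1`, `mean_forgotten_z`, `n_trials`,
#'   `converged`, `separation`, `reason`.
#' @export
memory_bias <- function(record, corrected = FALSE, min_trials = 10L) {
  vt <- value_terms(record)
  cls <- classify_decision_trials(record$decisions, record$recalls)
  one <- cls[cls$trial_type == "one_remembered", , drop = FALSE]
  forgotten <- record$recalls$snack_id[record$recalls$correct == 0L]
  mfz <- if (length(forgotten)) mean(vt$z[forgotten]) else NA_real_
  if (nrow(one) < min_trials) {
    out <- missing_bias("too few one-remembered trials", nrow(one))
    out$mean_forgotten_z <- mfz
    return(out)
  }
  chose_rem <- as.numeric((one$choice == "a" & one$rem_a) |
                            (one$choice == "b" & one$rem_b))
  z_rem <- ifelse(one$rem_a, vt$z[one$snack_a], vt$z[one$snack_b])
  x <- if (corrected) z_rem - mfz else z_rem
  fit <- tryCatch(
    fit_logistic_mle(cbind("(Intercept)" = 1, z_rem = x), chose_rem),
    membias_fit_error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- missing_bias("logistic fit failed", nrow(one))
    out$mean_forgotten_z <- mfz
    return(out)
  }
  if (fit$separation) {
    out <- missing_bias("separation in the bias regression", nrow(one))
    out$separation <- TRUE
    out$mean_forgotten_z <- mfz
    return(out)
  }
  tibble(b0 = unname(fit$coefficients[1]), b1 = unname(fit$coefficients[2]),
         mean_forgotten_z = mfz, n_trials = nrow(one),
         converged = fit$converged, separation = FALSE, reason = NA_character_)
}

# per-snack analysis table: z, q, recall count k, estimate
estimation_table <- function(record, vt = value_terms(record)) {
  k <- as.vector(rowsum(record$recalls$correct,
                        factor(record$recalls$snack_id, levels = vt$snack_id)))
  est <- record$estimates$estimate[match(vt$snack_id, record$estimates$snack_id)]
  tibble(snack_id = vt$snack_id, z = unname(vt$z), q = unname(vt$q),
         k = k, estimate = est)
}

#' Value-dependency regressions of estimation and performance
#'
#' Fits the per-participant regression of either the memory estimate (one
#' row per used snack, least squares on the 0-6 estimate treated as
#' continuous) or cued-recall performance (one row per snack-block recall,
#' logistic) on the standardized value `z` and/or its restandardized square
#' `q`. With `control_performance = TRUE` (estimation only) the actual
#' recall count `k` enters as a covariate, isolating the value effect on
#' estimation beyond what the participant actually remembered.
#'
#' @param record A `membias_participant`.
#' @param outcome `"estimation"` or `"performance"`.
#' @param terms Which value regressors to include.
#' @param control_performance Add the recall count `k` (estimation only).
#' @return A `membias_glm`.
#' @export
value_dependency <- function(record,
                             outcome = c("estimation", "performance"),
                             terms = c("linear+quadratic", "linear", "quadratic"),
                             control_performance = FALSE) {
  outcome <- match.arg(outcome)
  terms <- match.arg(terms)
  vt <- value_terms(record)
  if (outcome == "performance") {
    if (control_performance) {
      abort("control_performance applies to the estimation outcome only",
            class = "membias_config_error")
    }
    zi <- vt$z[record$recalls$snack_id]
    qi <- vt$q[record$recalls$snack_id]
    X <- cbind("(Intercept)" = 1,
               if (terms != "quadratic") cbind(z = zi),
               if (terms != "linear") cbind(q = qi))
    fit_logistic_mle(X, record$recalls$correct)
  } else {
    et <- estimation_table(record, vt)
    X <- cbind("(Intercept)" = 1,
               if (terms != "quadratic") cbind(z = et$z),
               if (terms != "linear") cbind(q = et$q),
               if (control_performance) cbind(k = et$k))
    fit_linear_ml(X, et$estimate)
  }
}

#' Mean memory estimate by recall count and value group
#'
#' Splits a participant's snacks by actual recall count (0-6) and by
#' whether their value lies above or below the participant's average, and
#' reports the mean estimate and cell count per combination; empty cells
#' are kept with `NA` means.
#'
#' @param record A `membias_participant`.
#' @return Tibble with `k`, `value_group` (`"below"`/`"above"`), `n`,
#'   `mean_estimate`.
#' @export
estimation_cell_means <- function(record) {
  et <- estimation_table(record)
  occurrences <- nrow(record$recalls) / length(unique(record$design$snack_id))
  et$value_group <- ifelse(et$z > 0, "above", "below")
  cells <- dplyr::summarise(
    dplyr::group_by(et, k = .data$k, value_group = .data$value_group),
    n = dplyr::n(), mean_estimate = mean(.data$estimate), .groups = "drop"
  )
  grid <- tidyr::expand_grid(k = 0:round(occurrences),
                             value_group = c("below", "above"))
  out <- dplyr::left_join(grid, cells, by = c("k", "value_group"))
  out$n[is.na(out$n)] <- 0L
  out
}

coef_or_na <- function(fit, term) {
  if (is.null(fit) || fit$separation) return(NA_real_)
  unname(fit$coefficients[term])
}

dev_or_na <- function(fit) {
  if (is.null(fit) || fit$separation) return(NA_real_)
  fit$deviance
}

safe_fit <- function(expr) {
  tryCatch(expr, membias_fit_error = function(e) NULL,
           membias_degenerate_error = function(e) NULL)
}

#' All per-participant coefficients of the analysis battery
#'
#' Computes, for every participant: the memory bias (`b0_h1`, slope
#' `b1_h1`) and its corrected variant, the mean standardized value of
#' forgotten options, the estimation-on-value slopes (linear-only and
#' linear+quadratic models), the performance-on-value logistic coefficients,
#' the performance-controlled estimation coefficients, and the deviances of
#' all fitted model variants (for the summed likelihood-ratio tests).
#' Participants whose fits are degenerate or separated get `NA` statistics
#' and a reason, never a silent drop.
#'
#' @param x A `membias_cohort`.
#' @param min_trials Minimum one-remembered trials for the bias regression.
#' @return Tibble with one row per participant.
#' @export
participant_coefficients <- function(x, min_trials = 10L) {
  recs <- participant_records(x)
  rows <- lapply(names(recs), function(id) {
    rec <- recs[[id]]
    base <- tibble(participant_id = id)
    vt <- tryCatch(value_terms(rec), membias_degenerate_error = function(e) NULL)
    if (!is.null(vt)) {
      return(dplyr::bind_cols(base, coefficient_row(rec, vt, min_trials)))
    }
    na_row <- tibble(
      b0_h1 = NA_real_, b1_h1 = NA_real_, b0_corrected = NA_real_,
      b1_corrected = NA_real_, mean_forgotten_z = NA_real_,
      n_one_remembered = NA_integer_, h1_separation = FALSE,
      b1_h2 = NA_real_, b1_h2_full = NA_real_, b_h2_quadratic = NA_real_,
      perf_linear = NA_real_, perf_quadratic = NA_real_,
      est_on_perf = NA_real_, est_on_value_ctrl = NA_real_,
      est_on_quad_ctrl = NA_real_,
      est_dev_lin = NA_real_, est_dev_quad = NA_real_, est_dev_full = NA_real_,
      perf_dev_lin = NA_real_, perf_dev_quad = NA_real_, perf_dev_full = NA_real_,
      recall_rate = mean(rec$recalls$correct),
      n_answered = sum(rec$decisions$choice != "missed"),
      rating_sd = 0, note = "zero rating variance"
    )
    dplyr::bind_cols(base, na_row)
  })
  dplyr::bind_rows(rows)
}

# shared-computation fast path for one participant: value terms, trial
# classification and the estimation table are computed once, all model
# variants reuse them; the corrected bias uses the exact reparameterization
# b0_corrected = b0 + b1 * mean_forgotten_z of the same likelihood
coefficient_row <- function(rec, vt, min_trials) {
  cls <- classify_decision_trials(rec$decisions, rec$recalls)
  one <- cls[cls$trial_type == "one_remembered", , drop = FALSE]
  forgotten <- rec$recalls$snack_id[rec$recalls$correct == 0L]
  mfz <- if (length(forgotten)) mean(vt$z[forgotten]) else NA_real_
  mb <- if (nrow(one) < min_trials) {
    missing_bias("too few one-remembered trials", nrow(one))
  } else {
    chose_rem <- as.numeric((one$choice == "a" & one$rem_a) |
                              (one$choice == "b" & one$rem_b))
    z_rem <- ifelse(one$rem_a, vt$z[one$snack_a], vt$z[one$snack_b])
    fit <- safe_fit(fit_logistic_mle(cbind("(Intercept)" = 1, z_rem = z_rem),
                                     chose_rem))
    if (is.null(fit)) {
      missing_bias("logistic fit failed", nrow(one))
    } else if (fit$separation) {
      out <- missing_bias("separation in the bias regression", nrow(one))
      out$separation <- TRUE
      out
    } else {
      tibble(b0 = unname(fit$coefficients[1]), b1 = unname(fit$coefficients[2]),
             n_trials = nrow(one), separation = FALSE, reason = NA_character_)
    }
  }

  et <- estimation_table(rec, vt)
  X_est <- cbind("(Intercept)" = 1, z = et$z, q = et$q, k = et$k)
  est_lin <- safe_fit(fit_linear_ml(X_est[, c(1, 2)], et$estimate))
  est_quad <- safe_fit(fit_linear_ml(X_est[, c(1, 3)], et$estimate))
  est_full <- safe_fit(fit_linear_ml(X_est[, 1:3], et$estimate))
  est_ctrl <- safe_fit(fit_linear_ml(X_est, et$estimate))

  zi <- vt$z[rec$recalls$snack_id]
  qi <- vt$q[rec$recalls$snack_id]
  X_perf <- cbind("(Intercept)" = 1, z = zi, q = qi)
  y_perf <- rec$recalls$correct
  perf_lin <- safe_fit(fit_logistic_mle(X_perf[, c(1, 2)], y_perf))
  perf_quad <- safe_fit(fit_logistic_mle(X_perf[, c(1, 3)], y_perf))
  perf_full <- safe_fit(fit_logistic_mle(X_perf, y_perf))

  tibble(
    b0_h1 = mb$b0, b1_h1 = mb$b1,
    b0_corrected = mb$b0 + mb$b1 * mfz, b1_corrected = mb$b1,
    mean_forgotten_z = mfz,
    n_one_remembered = mb$n_trials,
    h1_separation = mb$separation,
    b1_h2 = coef_or_na(est_lin, "z"),
    b1_h2_full = coef_or_na(est_full, "z"),
    b_h2_quadratic = coef_or_na(est_full, "q"),
    perf_linear = coef_or_na(perf_full, "z"),
    perf_quadratic = coef_or_na(perf_full, "q"),
    est_on_perf = coef_or_na(est_ctrl, "k"),
    est_on_value_ctrl = coef_or_na(est_ctrl, "z"),
    est_on_quad_ctrl = coef_or_na(est_ctrl, "q"),
    est_dev_lin = dev_or_na(est_lin),
    est_dev_quad = dev_or_na(est_quad),
    est_dev_full = dev_or_na(est_full),
    perf_dev_lin = dev_or_na(perf_lin),
    perf_dev_quad = dev_or_na(perf_quad),
    perf_dev_full = dev_or_na(perf_full),
    recall_rate = mean(y_perf),
    n_answered = sum(rec$decisions$choice != "missed"),
    rating_sd = sd(rec$ratings$rating[match(vt$snack_id, rec$ratings$snack_id)]),
    note = mb$reason
  )
}

#' Exclusion criteria for restricted-sample analyses
#'
#' Exclusion thresholds are study-specific, so all of them are
#' configurable; the defaults are all-permissive (exclude nobody).
#'
#' @param recall_rate_min,recall_rate_max Bounds on the cued-recall rate.
#' @param min_answered Minimum number of answered (non-missed) decisions.
#' @param min_rating_sd Minimum SD of the used snacks' ratings.
#' @param min_one_remembered Minimum usable one-remembered trials.
#' @return A list of class `membias_exclusions`.
#' @export
exclusion_criteria <- function(recall_rate_min = 0, recall_rate_max = 1,
                               min_answered = 0L, min_rating_sd = 0,
                               min_one_remembered = 0L) {
  structure(
    list(recall_rate_min = recall_rate_min, recall_rate_max = recall_rate_max,
         min_answered = as.integer(min_answered), min_rating_sd = min_rating_sd,
         min_one_remembered = as.integer(min_one_remembered)),
    class = "membias_exclusions"
  )
}

#' Apply exclusion criteria to a cohort
#'
#' @param x A `membias_cohort`.
#' @param criteria An [exclusion_criteria()] object.
#' @return List with `cohort` (participants passing all criteria) and
#'   `log` (tibble `participant_id`, `criterion`, `value` for every
#'   failed criterion).
#' @export
apply_exclusions <- function(x, criteria = exclusion_criteria()) {
  stopifnot(inherits(x, "membias_cohort"), inherits(criteria, "membias_exclusions"))
  recs <- participant_records(x)
  log_rows <- list()
  keep <- character(0)
  for (id in names(recs)) {
    rec <- recs[[id]]
    used <- unique(rec$design$snack_id)
    rr <- mean(rec$recalls$correct)
    n_ans <- sum(rec$decisions$choice != "missed")
    r_sd <- sd(rec$ratings$rating[match(used, rec$ratings$snack_id)])
    cls <- classify_decision_trials(rec$decisions, rec$recalls)
    n_one <- sum(cls$trial_type == "one_remembered")
    fails <- list()
    if (rr < criteria$recall_rate_min) fails$recall_rate_min <- rr
    if (rr > criteria$recall_rate_max) fails$recall_rate_max <- rr
    if (n_ans < criteria$min_answered) fails$min_answered <- n_ans
    if (is.na(r_sd) || r_sd < criteria$min_rating_sd) {
      fails$min_rating_sd <- r_sd %||% NA_real_
    }
    if (n_one < criteria$min_one_remembered) fails$min_one_remembered <- n_one
    if (length(fails)) {
      log_rows[[id]] <- tibble(participant_id = id, criterion = names(fails),
                               value = as.numeric(unlist(fails)))
    } else {
      keep <- c(keep, id)
    }
  }
  restricted <- x
  for (tab in cohort_tables) {
    restricted[[tab]] <- restricted[[tab]][restricted[[tab]]$participant_id %in% keep, ]
  }
  if (!is.null(restricted$true_params)) {
    restricted$true_params <-
      restricted$true_params[restricted$true_params$participant_id %in% keep, ]
  }
  restricted$provenance <- paste0(x$provenance, " [", length(keep), "/",
                                  length(recs), " kept after exclusions]")
  list(cohort = restricted,
       log = if (length(log_rows)) dplyr::bind_rows(log_rows)
             else tibble(participant_id = character(), criterion = character(),
                         value = numeric()))
}
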