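#' Per-participant path model of value, performance, and estimation
#'
#' Fits the recursive system relating standardized value (`z`), its
#' restandardized square (`q`), the actual recall count and the memory
#' estimate (all standardized within participant):
#' `performance ~ z + q` (paths `a1`, `a2`) and
#' `estimation ~ performance + z + q` (paths `b3`, `c1`, `c2`).
#' The system is just-identified and recursive, so per-equation least
#' squares is the exact maximum-likelihood solution; the indirect
#' (performance-mediated) effects are the products `a1*b3` and `a2*b3`.
#' With `include_strength = TRUE`, self-reported memory strength enters as
#' a parallel mediator: `strength ~ z + q` (`s1`, `s2`) and the estimation
#' equation gains a `strength` term (`b_str`).
#'
#' @param data Data frame with columns `z`, `q`, `k` (recall count),
#'   `estimate`, and `strength` when `include_strength = TRUE`; one row per
#'   used snack.
#' @param include_strength Add the strength mediator block.
#' @return One-row tibble of standardized path coefficients and mediation
#'   products (`NA` with a reason if any variable has zero variance).
#' @export
fit_participant_path <- function(data, include_strength = FALSE) {
  need <- c("z", "q", "k", "estimate", if (include_strength) "strength")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("path data lacks column(s): ", paste(miss, collapse = ", ")),
          class = "membias_config_error")
  }
  na_row <- tibble(
    a1 = NA_real_, a2 = NA_real_, b3 = NA_real_, c1 = NA_real_, c2 = NA_real_,
    indirect_z = NA_real_, indirect_q = NA_real_
  )
  if (include_strength) {
    na_row <- dplyr::bind_cols(na_row, tibble(
      s1 = NA_real_, s2 = NA_real_, b_str = NA_real_,
      indirect_z_strength = NA_real_, indirect_q_strength = NA_real_
    ))
  }
  std <- function(v) tryCatch(standardize_values(v),
                              membias_degenerate_error = function(e) NULL)
  perf <- std(data$k)
  est <- std(data$estimate)
  stren <- if (include_strength) std(data$strength) else NA
  if (is.null(perf) || is.null(est) || (include_strength && is.null(stren))) {
    na_row$reason <- "zero variance in a path variable"
    return(na_row)
  }
  X_zq <- cbind("(Intercept)" = 1, z = data$z, q = data$q)
  f_perf <- fit_linear_ml(X_zq, perf)
  if (include_strength) {
    f_str <- fit_linear_ml(X_zq, stren)
    f_est <- fit_linear_ml(cbind(X_zq, perf = perf, strength = stren), est)
    out <- tibble(
      a1 = unname(f_perf$coefficients["z"]),
      a2 = unname(f_perf$coefficients["q"]),
      b3 = unname(f_est$coefficients["perf"]),
      c1 = unname(f_est$coefficients["z"]),
      c2 = unname(f_est$coefficients["q"]),
      s1 = unname(f_str$coefficients["z"]),
      s2 = unname(f_str$coefficients["q"]),
      b_str = unname(f_est$coefficients["strength"])
    )
    out$indirect_z <- out$a1 * out$b3
    out$indirect_q <- out$a2 * out$b3
    out$indirect_z_strength <- out$s1 * out$b_str
    out$indirect_q_strength <- out$s2 * out$b_str
  } else {
    f_est <- fit_linear_ml(cbind(X_zq, perf = perf), est)
    out <- tibble(
      a1 = unname(f_perf$coefficients["z"]),
      a2 = unname(f_perf$coefficients["q"]),
      b3 = unname(f_est$coefficients["perf"]),
      c1 = unname(f_est$coefficients["z"]),
      c2 = unname(f_est$coefficients["q"])
    )
    out$indirect_z <- out$a1 * out$b3
    out$indirect_q <- out$a2 * out$b3
  }
  out$reason <- NA_character_
  out
}

#' Path coefficients for every participant of a cohort
#'
#' Builds each participant's per-snack table (z, q, recall count, estimate,
#' and mean strength rating when requested) and fits the path model of
#' [fit_participant_path()].
#'
#' @param x A `membias_cohort`.
#' @param include_strength Add the strength mediator block.
#' @return Tibble with `participant_id` and the path coefficients.
#' @export
path_coefficients <- function(x, include_strength = FALSE) {
  recs <- participant_records(x)
  rows <- lapply(names(recs), function(id) {
    rec <- recs[[id]]
    vt <- tryCatch(value_terms(rec), membias_degenerate_error = function(e) NULL)
    if (is.null(vt)) {
      out <- fit_participant_path(
        tibble(z = c(0, 0), q = c(0, 0), k = c(0, 0), estimate = c(0, 0),
               strength = c(0, 0)),
        include_strength = include_strength
      )
      out$reason <- "zero rating variance"
      return(dplyr::bind_cols(tibble(participant_id = id), out))
    }
    dat <- estimation_table(rec, vt)
    if (include_strength) {
      mean_str <- rowsum(rec$recalls$strength,
                         factor(rec$recalls$snack_id, levels = vt$snack_id))
      n_str <- rowsum(rep(1, nrow(rec$recalls)),
                      factor(rec$recalls$snack_id, levels = vt$snack_id))
      dat$strength <- as.vector(mean_str / n_str)
    }
    dplyr::bind_cols(tibble(participant_id = id),
                     fit_participant_path(dat, include_strength = include_strength))
  })
  dplyr::bind_rows(rows)
}

#' Group-level tests of the path coefficients
#'
#' One-sample t-test of each path coefficient against zero across
#' participants, with Cohen's d and a 95% CI.
#'
#' @param paths Output of [path_coefficients()].
#' @param sidedness Passed to [one_sample_t()] (two-sided by default, as
#'   the path analysis is exploratory).
#' @return Tibble with one row per coefficient.
#' @export
group_path_tests <- function(paths, sidedness = "two.sided") {
  coef_cols <- setdiff(names(paths), c("participant_id", "reason"))
  rows <- lapply(coef_cols, function(cl) {
    v <- paths[[cl]][is.finite(paths[[cl]])]
    if (length(v) < 3L) {
      abort(paste0("fewer than 3 participants with a non-missing ", cl),
            class = "membias_config_error")
    }
    res <- one_sample_t(v, mu0 = 0, sidedness = sidedness)
    dplyr::bind_cols(tibble(coefficient = cl), res)
  })
  dplyr::bind_rows(rows)
}

#' Correlation of path coefficients with the memory bias
#'
#' Tests whether the memory bias tracks the "true" value-dependency of
#' memory (the path `a1` from linear value to performance) or its
#' overestimation (the direct path `c1` from linear value to estimation),
#' via Pearson correlations across participants.
#'
#' @param paths Output of [path_coefficients()].
#' @param coefs Output of [participant_coefficients()] (for `b0_h1`).
#' @param sidedness Passed to [pearson_r()].
#' @return Two-row tibble (`a1_vs_bias`, `c1_vs_bias`) of correlation tests.
#' @export
correlate_paths_with_bias <- function(paths, coefs, sidedness = "two.sided") {
  m <- dplyr::inner_join(paths[c("participant_id", "a1", "c1")],
                         coefs[c("participant_id", "b0_h1")],
                         by = "participant_id")
  rows <- lapply(c(a1 = "a1", c1 = "c1"), function(cl) {
    ok <- is.finite(m[[cl]]) & is.finite(m$b0_h1)
    pearson_r(m[[cl]][ok], m$b0_h1[ok], sidedness = sidedness)
  })
  dplyr::bind_cols(tibble(pair = c("a1_vs_bias", "c1_vs_bias")),
                   dplyr::bind_rows(rows))
}
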