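#' Summed-deviance likelihood-ratio test across participants
#'
#' Per-participant regressions are compared by summing each participant's
#' deviance difference between a restricted model and the more general
#' model that nests it, and referring the sum to a chi-square distribution.
#' With one extra parameter per participant the default degrees of freedom
#' equal the number of participants; `df_convention = "n_minus_1"` matches
#' the convention in which the subscript is one less than the participant
#' count (the chi-square value itself is identical under both).
#'
#' @param deviance_restricted,deviance_full Per-participant deviances of
#'   the restricted and the general model (same participants, same order).
#'   Pairs with a missing value in either vector are dropped jointly.
#' @param participant_id Optional ids, checked for pairwise consistency
#'   when both fits carry them.
#' @param df_convention `"n"` (default) or `"n_minus_1"`.
#' @param label Optional comparison label carried into the output.
#' @return One-row tibble: `label`, `chi_sq`, `df`, `p`, `n_participants`,
#'   `df_convention`.
#' @export
summed_lrt <- function(deviance_restricted, deviance_full,
                       participant_id = NULL,
                       df_convention = c("n", "n_minus_1"),
                       label = NA_character_) {
  df_convention <- match.arg(df_convention)
  if (length(deviance_restricted) != length(deviance_full)) {
    abort("restricted and full fits cover different participants",
          class = "membias_config_error")
  }
  ok <- is.finite(deviance_restricted) & is.finite(deviance_full)
  dr <- deviance_restricted[ok]
  dfl <- deviance_full[ok]
  n <- length(dr)
  if (n < 1L) abort("no complete participant pairs", class = "membias_config_error")
  gaps <- dr - dfl
  if (any(gaps < -1e-6)) {
    bad <- which(gaps < -1e-6)[1]
    id <- if (!is.null(participant_id)) participant_id[ok][bad] else bad
    abort(paste0("full model fits worse than its restriction for participant ", id,
                 " (deviance gap ", format(gaps[bad]), "); models are not nested ",
                 "or a fit failed"),
          class = "membias_fit_error")
  }
  chi_sq <- sum(pmax(gaps, 0))
  df <- if (df_convention == "n") n else n - 1L
  tibble(label = label, chi_sq = chi_sq, df = df,
         p = pchisq(chi_sq, df, lower.tail = FALSE),
         n_participants = n, df_convention = df_convention)
}
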