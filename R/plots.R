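#' Effect-size overview of a results table
#'
#' Dot plot of Cohen's d (t-tests) and r (correlations) for every analysis
#' in the results table; chi-square model comparisons have no effect size
#' on this scale and are omitted.
#'
#' @param object A `membias_results`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot membias_results
#' @export
autoplot.membias_results <- function(object, ...) {
  tab <- object$table[object$table$statistic_type != "chisq", ]
  tab$analysis <- factor(tab$analysis, levels = rev(tab$analysis))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$effect_size, y = .data$analysis,
                                    shape = .data$statistic_type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(values = c(t = 16, r = 17),
                                labels = c(t = "Cohen's d", r = "Pearson r")) +
    ggplot2::labs(x = "effect size", y = NULL, shape = NULL,
                  title = paste0("Analysis battery (", object$sample, " sample)")) +
    ggplot2::theme_minimal()
}

#' Choice probability of the remembered option as a function of its value
#'
#' Reconstructs the group-level logistic curve of choosing the remembered
#' option (in one-remembered trials) over its standardized value, from the
#' per-participant bias regressions: thin lines are participants, the thick
#' line uses the mean intercept and slope. The vertical shift of the curve
#' at z = 0 above 0.5 is the memory bias.
#'
#' @param coefs Output of [participant_coefficients()].
#' @param z_range Range of standardized value to display.
#' @return A ggplot object.
#' @export
plot_bias_curve <- function(coefs, z_range = c(-2.5, 2.5)) {
  ok <- is.finite(coefs$b0_h1) & is.finite(coefs$b1_h1)
  coefs <- coefs[ok, ]
  z <- seq(z_range[1], z_range[2], length.out = 101)
  per <- dplyr::bind_rows(lapply(seq_len(nrow(coefs)), function(i) {
    tibble(participant_id = coefs$participant_id[i], z = z,
           p = plogis(coefs$b0_h1[i] + coefs$b1_h1[i] * z))
  }))
  grp <- tibble(z = z, p = plogis(mean(coefs$b0_h1) + mean(coefs$b1_h1) * z))
  ggplot2::ggplot(per, ggplot2::aes(x = .data$z, y = .data$p)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.15, color = "steelblue") +
    ggplot2::geom_line(data = grp, linewidth = 1.2, color = "black") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "standardized value of the remembered option",
                  y = "P(choose remembered option)") +
    ggplot2::theme_minimal()
}

#' Memory estimation and performance as functions of value
#'
#' Cohort-level means of the 0-6 memory estimate and of the recall rate
#' (rescaled to 0-6 for comparability) within bins of standardized value,
#' showing the U-shaped (linear + quadratic) value dependency.
#'
#' @param x A `membias_cohort`.
#' @param n_bins Number of value bins.
#' @return A ggplot object.
#' @export
plot_estimation_by_value <- function(x, n_bins = 8L) {
  recs <- participant_records(x)
  dat <- dplyr::bind_rows(lapply(recs, function(rec) {
    et <- tryCatch(estimation_table(rec), membias_degenerate_error = function(e) NULL)
    if (is.null(et)) return(NULL)
    et
  }))
  dat$bin <- cut(dat$z, breaks = n_bins)
  agg <- dplyr::summarise(
    dplyr::group_by(dat, .data$bin),
    z = mean(.data$z),
    `memory estimate` = mean(.data$estimate),
    `recall count` = mean(.data$k),
    .groups = "drop"
  )
  long <- tidyr::pivot_longer(agg, c("memory estimate", "recall count"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$value,
                                     color = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "standardized value", y = "mean per value bin (0-6)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
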