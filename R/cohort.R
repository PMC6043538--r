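#' Assemble a cohort from its component tables
#'
#' A cohort bundles the five long-format tables produced by the
#' remember-and-decide and estimate-your-memory tasks: snack ratings, the
#' block design (which snack sat on which screen location in which block),
#' cued-recall outcomes, paired decisions, and per-snack memory estimates.
#' All analysis entry points consume this container.
#'
#' @param ratings Tibble with columns `participant_id`, `snack_id`,
#'   `rating` (willingness to eat, 0-10), `adjusted` (logical; whether the
#'   post-review rating was used).
#' @param design Tibble with columns `participant_id`, `block`, `snack_id`,
#'   `location` (screen position 1-6).
#' @param recalls Tibble with columns `participant_id`, `block`, `snack_id`,
#'   `location`, `correct` (0/1), `strength` (self-reported memory strength,
#'   rescaled to 0-1).
#' @param decisions Tibble with columns `participant_id`, `block`, `trial`,
#'   `snack_a`, `snack_b`, `choice` (one of `"a"`, `"b"`, `"missed"`).
#' @param estimates Tibble with columns `participant_id`, `snack_id`,
#'   `estimate` (integer 0-6: how often, out of 6, the snack was judged to
#'   have been recalled).
#' @param provenance Free-text description of where the data came from
#'   (simulation seed and parameters, or file source).
#' @param validate Check all structural invariants (default `TRUE`).
#'
#' @return An object of class `membias_cohort`: a list of the five tibbles
#'   plus `provenance`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort <- function(ratings, design, recalls, decisions, estimates,
                   provenance = "unspecified", validate = TRUE) {
  x <- structure(
    list(
      ratings = as_tibble(ratings),
      design = as_tibble(design),
      recalls = as_tibble(recalls),
      decisions = as_tibble(decisions),
      estimates = as_tibble(estimates),
      provenance = provenance
    ),
    class = "membias_cohort"
  )
  if (validate) validate_cohort(x)
  x
}

#' @export
print.membias_cohort <- function(x, ...) {
  cat("<membias_cohort>\n")
  cat("  participants: ", dplyr::n_distinct(x$ratings$participant_id), "\n", sep = "")
  cat("  ratings: ", nrow(x$ratings),
      "  recalls: ", nrow(x$recalls),
      "  decisions: ", nrow(x$decisions),
      "  estimates: ", nrow(x$estimates), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Participant identifiers of a cohort
#' @param x A `membias_cohort`.
#' @return Character vector of unique participant ids, in first-appearance order.
#' @export
participants <- function(x) {
  stopifnot(inherits(x, "membias_cohort"))
  unique(x$ratings$participant_id)
}

cohort_tables <- c("ratings", "design", "recalls", "decisions", "estimates")

cohort_columns <- list(
  ratings = c("participant_id", "snack_id", "rating", "adjusted"),
  design = c("participant_id", "block", "snack_id", "location"),
  recalls = c("participant_id", "block", "snack_id", "location", "correct", "strength"),
  decisions = c("participant_id", "block", "trial", "snack_a", "snack_b", "choice"),
  estimates = c("participant_id", "snack_id", "estimate")
)

fail_validation <- function(...) {
  abort(paste0(...), class = "membias_validation_error")
}

#' Validate the structural invariants of a cohort
#'
#' Checks column layout, value ranges (ratings 0-10, strength 0-1,
#' estimates 0-6), uniqueness (one final rating per snack, one recall
#' outcome per block x snack, one estimate per used snack), and referential
#' consistency (decisions reference two distinct snacks from their block's
#' set; every used snack has one recall outcome per design appearance).
#'
#' @param x A `membias_cohort`.
#' @return `x`, invisibly. Throws a classed `membias_validation_error`
#'   naming the offending participant otherwise.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "membias_cohort"))
  for (tab in cohort_tables) {
    miss <- setdiff(cohort_columns[[tab]], names(x[[tab]]))
    if (length(miss)) {
      fail_validation(tab, " is missing column(s): ", paste(miss, collapse = ", "))
    }
  }
  r <- x$ratings
  if (nrow(r)) {
    bad <- r$rating < 0 | r$rating > 10 | !is.finite(r$rating)
    if (any(bad)) {
      fail_validation("rating outside [0, 10] for participant ",
                      r$participant_id[which(bad)[1]])
    }
    dup <- duplicated(r[c("participant_id", "snack_id")])
    if (any(dup)) {
      fail_validation("duplicate rating for participant ",
                      r$participant_id[which(dup)[1]], ", snack ",
                      r$snack_id[which(dup)[1]])
    }
  }
  d <- x$design
  if (nrow(d)) {
    per_block <- dplyr::summarise(
      dplyr::group_by(d, .data$participant_id, .data$block),
      n = dplyr::n(), n_distinct_snacks = dplyr::n_distinct(.data$snack_id),
      .groups = "drop"
    )
    bad <- per_block$n != per_block$n_distinct_snacks
    if (any(bad)) {
      fail_validation("duplicated snack within block ",
                      per_block$block[which(bad)[1]], " of participant ",
                      per_block$participant_id[which(bad)[1]])
    }
  }
  re <- x$recalls
  if (nrow(re)) {
    if (!all(re$correct %in% c(0L, 1L))) {
      fail_validation("recall `correct` must be 0 or 1 (participant ",
                      re$participant_id[which(!re$correct %in% c(0L, 1L))[1]], ")")
    }
    bad <- re$strength < 0 | re$strength > 1 | !is.finite(re$strength)
    if (any(bad)) {
      fail_validation("recall strength outside [0, 1] for participant ",
                      re$participant_id[which(bad)[1]])
    }
    # one outcome per (participant, block, snack), matching the design rows
    key_design <- paste(d$participant_id, d$block, d$snack_id)
    key_recall <- paste(re$participant_id, re$block, re$snack_id)
    if (anyDuplicated(key_recall)) {
      fail_validation("duplicate recall outcome for participant ",
                      re$participant_id[which(duplicated(key_recall))[1]])
    }
    if (!setequal(key_design, key_recall)) {
      off <- c(setdiff(key_design, key_recall), setdiff(key_recall, key_design))[1]
      fail_validation("recall outcomes do not match the design rows (", off, ")")
    }
  }
  dec <- x$decisions
  if (nrow(dec)) {
    if (any(dec$snack_a == dec$snack_b)) {
      fail_validation("decision pairs two copies of the same snack (participant ",
                      dec$participant_id[which(dec$snack_a == dec$snack_b)[1]], ")")
    }
    if (!all(dec$choice %in% c("a", "b", "missed"))) {
      fail_validation("decision choice must be one of 'a', 'b', 'missed'")
    }
    key_design <- paste(d$participant_id, d$block, d$snack_id)
    bad <- !(paste(dec$participant_id, dec$block, dec$snack_a) %in% key_design) |
      !(paste(dec$participant_id, dec$block, dec$snack_b) %in% key_design)
    if (any(bad)) {
      fail_validation("decision references a snack outside its block's set ",
                      "(participant ", dec$participant_id[which(bad)[1]],
                      ", block ", dec$block[which(bad)[1]], ")")
    }
  }
  es <- x$estimates
  if (nrow(es)) {
    bad <- !(es$estimate %in% 0:6)
    if (any(bad)) {
      fail_validation("memory estimate outside 0..6 for participant ",
                      es$participant_id[which(bad)[1]], ", snack ",
                      es$snack_id[which(bad)[1]])
    }
    key_est <- paste(es$participant_id, es$snack_id)
    if (anyDuplicated(key_est)) {
      fail_validation("duplicate memory estimate for participant ",
                      es$participant_id[which(duplicated(key_est))[1]])
    }
    used <- unique(paste(d$participant_id, d$snack_id))
    if (!setequal(used, key_est)) {
      off <- c(setdiff(used, key_est), setdiff(key_est, used))[1]
      fail_validation("estimates must cover exactly the used snacks (", off, ")")
    }
  }
  invisible(x)
}

cohort_sort <- function(x) {
  x$ratings <- dplyr::arrange(x$ratings, .data$participant_id, .data$snack_id)
  x$design <- dplyr::arrange(x$design, .data$participant_id, .data$block, .data$location)
  x$recalls <- dplyr::arrange(x$recalls, .data$participant_id, .data$block, .data$location)
  x$decisions <- dplyr::arrange(x$decisions, .data$participant_id, .data$block, .data$trial)
  x$estimates <- dplyr::arrange(x$estimates, .data$participant_id, .data$snack_id)
  x
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `ratings.csv`, `design.csv`, `recalls.csv`, `decisions.csv` and
#' `estimates.csv` (UTF-8, header row, `.` decimal separator) with a
#' deterministic row and column order, so identical cohorts produce
#' byte-identical bundles.
#'
#' @param x A `membias_cohort`.
#' @param path Directory to write into (created if absent).
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "membias_cohort"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", path), class = "membias_io_error")
  }
  x <- cohort_sort(x)
  for (tab in cohort_tables) {
    readr::write_csv(x[[tab]][cohort_columns[[tab]]],
                     file.path(path, paste0(tab, ".csv")), progress = FALSE)
  }
  if (!is.null(x$true_params)) {
    readr::write_csv(dplyr::arrange(x$true_params, .data$participant_id),
                     file.path(path, "params.csv"), progress = FALSE)
  }
  invisible(x)
}

cohort_col_types <- list(
  ratings = readr::cols(
    participant_id = readr::col_character(), snack_id = readr::col_character(),
    rating = readr::col_double(), adjusted = readr::col_logical()
  ),
  design = readr::cols(
    participant_id = readr::col_character(), block = readr::col_integer(),
    snack_id = readr::col_character(), location = readr::col_integer()
  ),
  recalls = readr::cols(
    participant_id = readr::col_character(), block = readr::col_integer(),
    snack_id = readr::col_character(), location = readr::col_integer(),
    correct = readr::col_integer(), strength = readr::col_double()
  ),
  decisions = readr::cols(
    participant_id = readr::col_character(), block = readr::col_integer(),
    trial = readr::col_integer(), snack_a = readr::col_character(),
    snack_b = readr::col_character(), choice = readr::col_character()
  ),
  estimates = readr::cols(
    participant_id = readr::col_character(), snack_id = readr::col_character(),
    estimate = readr::col_integer()
  )
)

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param path Directory containing the five CSV files.
#' @param validate Check invariants after reading (default `TRUE`).
#' @return A `membias_cohort` with `provenance` set to the source path.
#' @export
read_cohort <- function(path, validate = TRUE) {
  files <- file.path(path, paste0(cohort_tables, ".csv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    abort(paste0("cohort bundle is missing: ",
                 paste(basename(files[missing]), collapse = ", ")),
          class = "membias_io_error")
  }
  tabs <- lapply(cohort_tables, function(tab) {
    readr::read_csv(file.path(path, paste0(tab, ".csv")),
                    col_types = cohort_col_types[[tab]], progress = FALSE)
  })
  names(tabs) <- cohort_tables
  out <- cohort(tabs$ratings, tabs$design, tabs$recalls, tabs$decisions,
                tabs$estimates,
                provenance = paste0("read from ", path), validate = validate)
  params_file <- file.path(path, "params.csv")
  if (file.exists(params_file)) {
    out$true_params <- readr::read_csv(params_file, show_col_types = FALSE,
                                       progress = FALSE)
  }
  out
}
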