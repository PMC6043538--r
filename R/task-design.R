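#' Configuration of the remember-and-decide block design
#'
#' Defaults reproduce the study task: 24 blocks of 6 snacks, each used snack
#' occurring exactly 6 times, 9 decision pairs per block, the 6 top-rated
#' "favorite" snacks excluded before selection, and the remaining pool
#' stratified into 3 value tiers.
#'
#' @param n_blocks Number of blocks.
#' @param set_size Snacks (and screen locations) per block.
#' @param occurrences How many blocks each used snack appears in.
#' @param n_pairs Decision pairs per block.
#' @param n_excluded_favorites Top-rated snacks removed before selection.
#' @param value_tiers Number of value strata; every block must contain at
#'   least one snack from each tier.
#' @param max_consecutive_repeats Target number of snack repetitions in
#'   consecutive blocks (0 = never repeat across adjacent blocks).
#' @param max_restarts Restarts of the randomized greedy assignment before
#'   relaxing the consecutive-repeat constraint.
#' @return A list of class `membias_design_config`.
#' @export
design_config <- function(n_blocks = 24L, set_size = 6L, occurrences = 6L,
                          n_pairs = 9L, n_excluded_favorites = 6L,
                          value_tiers = 3L, max_consecutive_repeats = 0L,
                          max_restarts = 100L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks), set_size = as.integer(set_size),
    occurrences = as.integer(occurrences), n_pairs = as.integer(n_pairs),
    n_excluded_favorites = as.integer(n_excluded_favorites),
    value_tiers = as.integer(value_tiers),
    max_consecutive_repeats = as.integer(max_consecutive_repeats),
    max_restarts = as.integer(max_restarts)
  )
  if ((cfg$n_blocks * cfg$set_size) %% cfg$occurrences != 0L) {
    abort("n_blocks * set_size must be divisible by occurrences",
          class = "membias_config_error")
  }
  if (cfg$n_pairs > choose(cfg$set_size, 2)) {
    abort("n_pairs exceeds the number of distinct pairs in a block",
          class = "membias_config_error")
  }
  if (cfg$value_tiers > cfg$set_size) {
    abort("value_tiers cannot exceed set_size (tier mix would be infeasible)",
          class = "membias_config_error")
  }
  structure(cfg, class = "membias_design_config")
}

resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Schedule the decision pairs of one block
#'
#' Draws `n_pairs` distinct unordered pairs from a block's snack set. When a
#' balanced schedule exists (each snack appearing in exactly
#' `2 * n_pairs / set_size` pairs) one is sampled uniformly; for the default
#' geometry (6 snacks, 9 pairs) this is a random 3-regular graph on the 6
#' snacks, drawn exactly as the complement of a uniform 2-regular graph.
#' When no balanced schedule exists the function falls back to unbalanced
#' random sampling with a warning.
#'
#' @param snacks Character vector of the block's snack ids.
#' @param n_pairs Number of pairs to schedule.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Tibble with columns `snack_a`, `snack_b` (`n_pairs` rows, row and
#'   within-pair order randomized).
#' @export
schedule_decision_pairs <- function(snacks, n_pairs, seed = NULL) {
  s <- length(snacks)
  if (anyDuplicated(snacks)) abort("snacks must be distinct", class = "membias_config_error")
  if (n_pairs > choose(s, 2)) {
    abort("n_pairs exceeds the number of distinct pairs", class = "membias_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- schedule_pairs_idx(s, n_pairs)
  tibble(snack_a = snacks[idx[, 1]], snack_b = snacks[idx[, 2]])
}

# index-level scheduler shared by schedule_decision_pairs and the design
# builder; returns an n_pairs x 2 matrix with randomized row and a/b order
schedule_pairs_idx <- function(s, n_pairs, all_pairs = combn(s, 2)) {
  if (n_pairs == ncol(all_pairs)) {
    idx <- matrix(c(all_pairs[1, ], all_pairs[2, ]), ncol = 2)
  } else if ((2L * n_pairs) %% s == 0L) {
    d <- (2L * n_pairs) %/% s
    if (s == 6L && d == 3L) {
      idx <- pairs_regular_6_3()
    } else {
      idx <- pairs_regular_greedy(all_pairs, d, n_pairs)
      if (is.null(idx)) {
        warn("no balanced pair schedule found; falling back to random sampling")
        idx <- t(all_pairs[, sample.int(ncol(all_pairs), n_pairs)])
      }
    }
  } else {
    warn("no balanced pair schedule exists for these counts; sampling at random")
    idx <- t(all_pairs[, sample.int(ncol(all_pairs), n_pairs)])
  }
  idx <- idx[sample.int(nrow(idx)), , drop = FALSE]
  flip <- runif(nrow(idx)) < 0.5
  cbind(ifelse(flip, idx[, 2], idx[, 1]), ifelse(flip, idx[, 1], idx[, 2]))
}

# Uniform 3-regular graph on 6 labeled vertices via complement of a uniform
# 2-regular graph (a single 6-cycle w.p. 60/70, else two disjoint triangles).
pairs_regular_6_3 <- function() {
  p <- sample.int(6L)
  if (runif(1) < 60 / 70) {
    drop_a <- p
    drop_b <- p[c(2:6, 1)]
  } else {
    drop_a <- p[c(1, 2, 3, 4, 5, 6)]
    drop_b <- p[c(2, 3, 1, 5, 6, 4)]
  }
  keep <- matrix(TRUE, 6, 6)
  keep[cbind(drop_a, drop_b)] <- FALSE
  keep[cbind(drop_b, drop_a)] <- FALSE
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  unname(idx[, c(1, 2), drop = FALSE])
}

pairs_regular_greedy <- function(all_pairs, d, n_pairs, tries = 200L) {
  s <- max(all_pairs)
  for (t in seq_len(tries)) {
    ord <- sample.int(ncol(all_pairs))
    deg <- integer(s)
    picked <- integer(0)
    for (j in ord) {
      i1 <- all_pairs[1, j]; i2 <- all_pairs[2, j]
      if (deg[i1] < d && deg[i2] < d) {
        picked <- c(picked, j)
        deg[i1] <- deg[i1] + 1L
        deg[i2] <- deg[i2] + 1L
        if (length(picked) == n_pairs) break
      }
    }
    if (length(picked) == n_pairs) {
      return(t(all_pairs[, picked, drop = FALSE]))
    }
  }
  NULL
}

# Greedy block assignment: returns n_blocks x set_size matrix of snack
# indices, or NULL on dead-end. `no_consec` forbids adjacent-block repeats.
assign_blocks_once <- function(n_snacks, tier, cfg, no_consec) {
  remaining <- rep(cfg$occurrences, n_snacks)
  prev <- integer(0)
  out <- matrix(NA_integer_, cfg$n_blocks, cfg$set_size)
  for (b in seq_len(cfg$n_blocks)) {
    blocks_left <- cfg$n_blocks - b + 1L
    cand <- which(remaining > 0L)
    if (no_consec) cand <- setdiff(cand, prev)
    if (length(cand) < cfg$set_size) return(NULL)
    # snacks that must appear in every remaining block
    sel <- cand[remaining[cand] >= blocks_left]
    if (length(sel) > cfg$set_size) return(NULL)
    # guarantee one snack from each value tier
    for (tr in seq_len(cfg$value_tiers)) {
      if (!any(tier[sel] == tr)) {
        pool <- cand[tier[cand] == tr & !(cand %in% sel)]
        if (!length(pool)) return(NULL)
        pool <- pool[remaining[pool] == max(remaining[pool])]
        sel <- c(sel, resample(pool, 1L))
      }
    }
    if (length(sel) > cfg$set_size) return(NULL)
    # fill the rest, preferring snacks with the most appearances left
    while (length(sel) < cfg$set_size) {
      pool <- setdiff(cand, sel)
      if (!length(pool)) return(NULL)
      pool <- pool[remaining[pool] == max(remaining[pool])]
      sel <- c(sel, resample(pool, 1L))
    }
    out[b, ] <- resample(sel)
    remaining[sel] <- remaining[sel] - 1L
    prev <- sel
  }
  if (any(remaining != 0L)) return(NULL)
  out
}

consecutive_repeats <- function(block_matrix) {
  n <- nrow(block_matrix)
  if (n < 2L) return(0L)
  sum(vapply(seq_len(n - 1L), function(b) {
    length(intersect(block_matrix[b, ], block_matrix[b + 1L, ]))
  }, integer(1)))
}

#' Build the trial sets for one participant
#'
#' Implements the constrained randomization of the remember-and-decide task:
#' the `n_excluded_favorites` top-rated snacks are set aside (memory for
#' favorites is exceptionally good), the required number of used snacks is
#' drawn stratified across value tiers of the remaining pool, and snacks are
#' assigned to blocks by a randomized greedy algorithm so that each used
#' snack occurs exactly `occurrences` times, every block mixes all value
#' tiers, and repeats across adjacent blocks are avoided (minimized with a
#' warning if no repeat-free assignment is found within `max_restarts`).
#' Screen locations are re-randomized per block, with every used snack
#' guaranteed to appear on at least two distinct locations across the
#' experiment; decision pairs come from [schedule_decision_pairs()].
#'
#' @param ratings Tibble with `snack_id` and `rating` for one participant.
#' @param config A [design_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `membias_design`: list with `blocks` (tibble
#'   `block`, `snack_id`, `location`), `pairs` (tibble `block`, `trial`,
#'   `snack_a`, `snack_b`), `used_snacks` (tibble `snack_id`, `rating`,
#'   `tier`), `consecutive_repeats`, and `config`.
#' @export
build_trial_sets <- function(ratings, config = design_config(), seed = NULL) {
  stopifnot(inherits(config, "membias_design_config"))
  if (!is.null(seed)) set.seed(seed)
  ratings <- as_tibble(ratings)
  n_used <- (config$n_blocks * config$set_size) %/% config$occurrences
  if (nrow(ratings) < config$n_excluded_favorites + n_used) {
    abort(paste0("need at least ", config$n_excluded_favorites + n_used,
                 " rated snacks, got ", nrow(ratings)),
          class = "membias_config_error")
  }
  # stable order: by descending rating, ties by snack id
  ord <- order(-ratings$rating, ratings$snack_id)
  pool <- ratings[ord, , drop = FALSE]
  if (config$n_excluded_favorites > 0L) {
    pool <- pool[-seq_len(config$n_excluded_favorites), , drop = FALSE]
  }
  # value tiers on the remaining pool (tier 1 = highest rated)
  tier_pool <- cut(seq_len(nrow(pool)), breaks = config$value_tiers, labels = FALSE)
  # stratified selection of the used snacks, as even as possible across tiers
  per_tier <- rep(n_used %/% config$value_tiers, config$value_tiers)
  extra <- n_used - sum(per_tier)
  if (extra > 0L) {
    bump <- resample(seq_len(config$value_tiers), extra)
    per_tier[bump] <- per_tier[bump] + 1L
  }
  sel_idx <- unlist(lapply(seq_len(config$value_tiers), function(tr) {
    idx <- which(tier_pool == tr)
    if (length(idx) < per_tier[tr]) {
      abort("too few snacks in a value tier for stratified selection",
            class = "membias_config_error")
    }
    resample(idx, per_tier[tr])
  }))
  used <- pool[sel_idx, , drop = FALSE]
  tier <- tier_pool[sel_idx]

  block_matrix <- NULL
  for (r in seq_len(config$max_restarts)) {
    block_matrix <- assign_blocks_once(nrow(used), tier, config, no_consec = TRUE)
    if (!is.null(block_matrix)) break
  }
  if (is.null(block_matrix)) {
    # relax the adjacency constraint; keep the attempt with fewest repeats
    best <- NULL
    for (r in seq_len(max(20L, config$max_restarts %/% 5L))) {
      cand <- assign_blocks_once(nrow(used), tier, config, no_consec = FALSE)
      if (!is.null(cand) &&
          (is.null(best) || consecutive_repeats(cand) < consecutive_repeats(best))) {
        best <- cand
        if (consecutive_repeats(best) <= config$max_consecutive_repeats) break
      }
    }
    if (is.null(best)) {
      abort("block assignment failed even without the adjacency constraint",
            class = "membias_design_error")
    }
    warn(paste0("no repeat-free assignment found; best has ",
                consecutive_repeats(best), " consecutive repeat(s)"))
    block_matrix <- best
  }

  loc <- location_assignment(block_matrix, config)

  blocks <- tibble(
    block = rep(seq_len(config$n_blocks), each = config$set_size),
    snack_id = used$snack_id[as.vector(t(block_matrix))],
    location = as.vector(t(loc))
  )
  all_pairs <- combn(config$set_size, 2)
  pair_idx <- lapply(seq_len(config$n_blocks), function(b) {
    idx <- schedule_pairs_idx(config$set_size, config$n_pairs, all_pairs)
    cbind(block_matrix[b, idx[, 1]], block_matrix[b, idx[, 2]])
  })
  pair_mat <- do.call(rbind, pair_idx)
  pairs <- tibble(
    block = rep(seq_len(config$n_blocks), each = config$n_pairs),
    trial = rep(seq_len(config$n_pairs), config$n_blocks),
    snack_a = used$snack_id[pair_mat[, 1]],
    snack_b = used$snack_id[pair_mat[, 2]]
  )

  structure(
    list(
      blocks = blocks,
      pairs = pairs,
      used_snacks = tibble(snack_id = used$snack_id, rating = used$rating, tier = tier),
      consecutive_repeats = consecutive_repeats(block_matrix),
      config = config
    ),
    class = "membias_design"
  )
}

# Random location permutation per block; redraw until every snack has seen
# at least two distinct locations across its appearances.
location_assignment <- function(block_matrix, cfg, max_fixups = 1000L) {
  n_blocks <- nrow(block_matrix)
  loc <- t(vapply(seq_len(n_blocks), function(b) sample.int(cfg$set_size),
                  integer(cfg$set_size)))
  if (cfg$occurrences < 2L) return(loc)
  for (i in seq_len(max_fixups)) {
    n_loc <- tapply(as.vector(loc), as.vector(block_matrix),
                    function(l) length(unique(l)))
    stuck <- as.integer(names(n_loc)[n_loc < 2L])
    if (!length(stuck)) return(loc)
    # reshuffle one block containing the first offending snack
    b <- resample(which(apply(block_matrix == stuck[1], 1, any)), 1L)
    loc[b, ] <- sample.int(cfg$set_size)
  }
  abort("could not satisfy the two-distinct-locations constraint",
        class = "membias_design_error")
}

#' Check a block design against its constraints
#'
#' Report-only companion of [build_trial_sets()]: evaluates each design
#' constraint and returns one row per constraint with a pass flag and a
#' human-readable detail string. Hard constraints are the exact occurrence
#' count, distinct snacks per block, the per-block value-tier mix, pair
#' validity, and location diversity; the consecutive-repeat count is
#' compared against the configured target.
#'
#' @param design A `membias_design`.
#' @param config A [design_config()]; defaults to the design's own.
#' @return Tibble with columns `constraint`, `pass`, `count`, `detail`.
#' @export
validate_design <- function(design, config = design$config) {
  stopifnot(inherits(design, "membias_design"))
  blocks <- design$blocks
  occ <- table(blocks$snack_id)
  bad_occ <- names(occ)[occ != config$occurrences]
  per_block <- tapply(blocks$snack_id, blocks$block, function(s) length(unique(s)))
  bad_size <- sum(per_block != config$set_size)
  tier_of <- setNames(design$used_snacks$tier, design$used_snacks$snack_id)
  tier_ok <- tapply(blocks$snack_id, blocks$block, function(s) {
    length(unique(tier_of[s])) >= config$value_tiers
  })
  n_loc <- tapply(blocks$location, blocks$snack_id, function(l) length(unique(l)))
  bad_loc <- names(n_loc)[n_loc < 2L]
  bm <- matrix(match(blocks$snack_id, design$used_snacks$snack_id),
               nrow = config$n_blocks, byrow = TRUE)
  n_consec <- consecutive_repeats(bm)
  pr <- design$pairs
  pair_in_block <- vapply(seq_len(nrow(pr)), function(i) {
    s <- blocks$snack_id[blocks$block == pr$block[i]]
    pr$snack_a[i] %in% s && pr$snack_b[i] %in% s && pr$snack_a[i] != pr$snack_b[i]
  }, logical(1))
  pair_key <- paste(pr$block, pmin(pr$snack_a, pr$snack_b), pmax(pr$snack_a, pr$snack_b))
  n_pair_dup <- sum(duplicated(pair_key))

  tibble(
    constraint = c("occurrences", "set_size", "tier_mix", "consecutive_repeats",
                   "location_diversity", "pairs_valid", "pairs_distinct"),
    pass = c(!length(bad_occ), bad_size == 0L, all(tier_ok),
             n_consec <= config$max_consecutive_repeats,
             !length(bad_loc), all(pair_in_block), n_pair_dup == 0L),
    count = c(length(bad_occ), bad_size, sum(!tier_ok), n_consec,
              length(bad_loc), sum(!pair_in_block), n_pair_dup),
    detail = c(
      if (length(bad_occ)) paste("off-count snack(s):", paste(bad_occ, collapse = ", "))
      else sprintf("all snacks occur exactly %d times", config$occurrences),
      sprintf("%d block(s) with wrong set size", bad_size),
      sprintf("%d block(s) missing a value tier", sum(!tier_ok)),
      sprintf("%d snack repetition(s) across adjacent blocks", n_consec),
      if (length(bad_loc)) paste("single-location snack(s):", paste(bad_loc, collapse = ", "))
      else "every snack on >= 2 distinct locations",
      sprintf("%d pair(s) referencing snacks outside their block", sum(!pair_in_block)),
      sprintf("%d duplicated pair(s) within a block", n_pair_dup)
    )
  )
}
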