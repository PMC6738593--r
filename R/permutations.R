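# Manly/Bejder permutation tests for preferred/avoided companionship.

# shared post-processing: add-one p-values in the documented direction
perm_pvalue <- function(observed, null_values, tail = c("right", "left")) {
  tail <- match.arg(tail)
  n <- length(null_values)
  extreme <- if (tail == "right") sum(null_values >= observed)
             else sum(null_values <= observed)
  (1 + extreme) / (1 + n)
}

perm_result <- function(statistic_name, observed, null_values, tail,
                        n_perm, trials, seed, degenerate = FALSE) {
  structure(list(
    statistic_name = statistic_name,
    observed = observed,
    null_values = null_values,
    p = if (degenerate) NA_real_ else perm_pvalue(observed, null_values, tail),
    tail = tail,
    significant_05 = NA,
    significant_10 = NA,
    n_perm = n_perm, trials = trials, seed = seed,
    degenerate = degenerate
  ), class = "permutation_result")
}

finish_result <- function(res) {
  if (!res$degenerate) {
    res$significant_05 <- res$p < 0.05
    res$significant_10 <- res$p < 0.1
  }
  res
}

# encode a group table for the C chains
encode_groups <- function(groups, individuals) {
  days <- sort(unique(groups$sampling_day))
  g_split <- split(groups, groups$group_id)
  group_day <- vapply(g_split, function(g) {
    match(g$sampling_day[1], days) - 1L
  }, 0L)
  group_members <- lapply(g_split, function(g) {
    match(unique(g$individual_id), individuals) - 1L
  })
  seen <- unique(groups[c("individual_id", "sampling_day")])
  days_seen <- tabulate(match(seen$individual_id, individuals),
                        nbins = length(individuals))
  list(group_day = unname(group_day), group_members = unname(group_members),
       days_seen = days_seen)
}

#' Group-swap permutation test (within days)
#'
#' Tests the null hypothesis of no preferred or avoided companions by
#' sequential checkerboard swaps of individuals between same-day groups: the
#' chain holds constant the number of groups each individual was observed in
#' each day and the size of those groups, but not individual gregariousness.
#' Isolates are excluded before permuting, as this method is sensitive to
#' their inclusion. The chain is cumulative (Markov): `trials` swap attempts
#' separate saved statistic evaluations, with one extra block of `trials`
#' attempts as burn-in.
#'
#' Three statistics are evaluated on the SRI matrix rebuilt from the permuted
#' groups (masked dyads excluded):
#' * `cv_sri` (right tail): a high observed CV marks long-term preferred
#'   *and* avoided companionships;
#' * `mean_sri` (left tail): a low observed mean marks short-term,
#'   within-day preferred companions;
#' * `sd_gregariousness` (right tail): sd across individuals of the mean
#'   number of conspecifics encountered per day; a high observed value marks
#'   individual differences in gregariousness.
#'
#' @param groups a group table.
#' @param n_perm saved permutations (default 5000).
#' @param trials swap attempts between saved evaluations (default 1000).
#' @param seed integer seed.
#' @return list of three `permutation_result` objects (`cv_sri`, `mean_sri`,
#'   `sd_gregariousness`). If no legal swap exists the network is too sparse
#'   to permute and each result carries `degenerate = TRUE` and `p = NA`.
#' @export
permute_groups_within_days <- function(groups, n_perm = 5000, trials = 1000,
                                       seed = 1L) {
  check_count(n_perm, "n_perm")
  check_count(trials, "trials")
  iso <- isolates(groups)
  groups <- groups[!groups$individual_id %in% iso, , drop = FALSE]
  individuals <- sort(unique(groups$individual_id))
  names <- c("cv_sri", "mean_sri", "sd_gregariousness")
  tails <- c("right", "left", "right")
  if (length(individuals) < 3) {
    res <- lapply(seq_along(names), function(k) {
      perm_result(names[k], NA_real_, numeric(0), tails[k], n_perm, trials,
                  seed, degenerate = TRUE)
    })
    names(res) <- names
    return(res)
  }
  counts <- tally_dyads(groups, individuals)
  enc <- encode_groups(groups, individuals)
  out <- with_seed(seed, cpp_group_chain(
    enc$group_members, enc$group_day,
    length(individuals), counts$d, enc$days_seen,
    as.integer(n_perm), as.integer(trials), as.integer(trials)))
  res <- lapply(seq_along(names), function(k) {
    finish_result(perm_result(
      names[k], out$observed[k],
      if (out$degenerate) numeric(0) else out$null[, k],
      tails[k], n_perm, trials, seed, degenerate = out$degenerate
    ))
  })
  names(res) <- names
  # final chain state, for auditing the swap invariants
  attr(res, "chain") <- list(individuals = individuals,
                             group_day = enc$group_day,
                             initial_members = enc$group_members,
                             final_members = out$final_members)
  res
}

#' Association-swap permutation test (within days)
#'
#' Permutes dyadic associations, rather than groups, within days: two
#' same-day day-level association records with four distinct individuals
#' exchange partners, preserving each individual's daily association count.
#' This controls for gregariousness, so a significant result cannot be an
#' artefact of individuals differing in their overall tendency to associate;
#' the variant detects only long-term (between-day) preferred and avoided
#' companionships and needs considerably more data. Isolates are retained.
#'
#' @inheritParams permute_groups_within_days
#' @return a single `permutation_result` for `cv_sri` (right tail), or a
#'   degenerate result when the network is too sparse to permute.
#' @export
permute_associations_within_days <- function(groups, n_perm = 5000,
                                             trials = 1000, seed = 1L) {
  check_count(n_perm, "n_perm")
  check_count(trials, "trials")
  individuals <- sort(unique(groups$individual_id))
  counts <- tally_dyads(groups, individuals)
  # day-level dyadic records
  days <- sort(unique(groups$sampling_day))
  edges <- day_edge_list(groups, individuals, days)
  if (nrow(edges) < 2) {
    return(perm_result("cv_sri", NA_real_, numeric(0), "right", n_perm,
                       trials, seed, degenerate = TRUE))
  }
  out <- with_seed(seed, cpp_assoc_chain(
    edges$day - 1L, edges$i - 1L, edges$j - 1L,
    length(individuals), counts$d,
    as.integer(n_perm), as.integer(trials), as.integer(trials)))
  res <- finish_result(perm_result(
    "cv_sri", out$observed,
    if (out$degenerate) numeric(0) else out$null,
    "right", n_perm, trials, seed, degenerate = out$degenerate
  ))
  attr(res, "chain") <- list(
    individuals = individuals, initial = edges,
    final = if (out$degenerate) NULL else
      data.frame(day = edges$day, i = out$final_i + 1L,
                 j = out$final_j + 1L))
  res
}

# unique (day, i, j) day-level association records
day_edge_list <- function(groups, individuals, days) {
  recs <- list()
  k <- 0
  for (g in split(groups, groups$group_id)) {
    members <- match(unique(g$individual_id), individuals)
    if (length(members) >= 2) {
      pr <- t(utils::combn(sort(members), 2))
      k <- k + 1
      recs[[k]] <- data.frame(day = match(g$sampling_day[1], days),
                              i = pr[, 1], j = pr[, 2])
    }
  }
  if (k == 0) return(data.frame(day = integer(0), i = integer(0),
                                j = integer(0)))
  unique(do.call(rbind, recs))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s (%s tail)\n", x$statistic_name, x$tail))
  if (x$degenerate) {
    cat("  network too sparse to permute\n")
  } else {
    cat(sprintf("  observed = %.4f, null mean = %.4f, p = %.4g (n_perm = %d)\n",
                x$observed, mean(x$null_values), x$p, x$n_perm))
  }
  invisible(x)
}

#' Tabulate permutation results
#'
#' @param results a (possibly nested) list of `permutation_result` objects.
#' @param network_id identifier column value.
#' @return data.frame with one row per statistic, mirroring the CSV report
#'   layout (network id, statistic, observed, p, n_perm, trials, seed,
#'   degenerate flag).
#' @export
permutation_table <- function(results, network_id = "network") {
  if (inherits(results, "permutation_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(network_id = network_id, statistic = r$statistic_name,
               observed = r$observed, p = r$p, n_perm = r$n_perm,
               trials = r$trials, seed = r$seed, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
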