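# Matrix correlation tests (Mantel z, Dietz R), matched matrices across
# seasons, and Fisher omnibus p-value combination.

#' Restrict two association matrices to their shared individuals
#'
#' Matched matrices only contain individuals observed in both networks, in a
#' common ordering.
#'
#' @param netA,netB `association_matrix` objects.
#' @param min_shared minimum shared individuals (default 3).
#' @return list with the two restricted `association_matrix` objects and
#'   `shared` ids.
#' @export
match_matrices <- function(netA, netB, min_shared = 3) {
  shared <- intersect(netA$individuals, netB$individuals)
  if (length(shared) < min_shared) {
    stop_named("netA/netB", sprintf(
      "only %d shared individuals (need >= %d)", length(shared), min_shared))
  }
  restrict <- function(m) {
    idx <- match(shared, m$individuals)
    structure(list(individuals = shared,
                   sri = m$sri[idx, idx, drop = FALSE],
                   d = m$d[idx, idx, drop = FALSE],
                   mask = m$mask[idx, idx, drop = FALSE]),
              class = "association_matrix")
  }
  list(mA = restrict(netA), mB = restrict(netB), shared = shared)
}

#' Mantel permutation test between two matched matrices
#'
#' Correlates the off-diagonal entries of two square symmetric matrices; the
#' null distribution comes from simultaneous row-and-column permutation of
#' the second matrix. `kind = "mantel_z"` uses the Pearson product-moment
#' correlation; `kind = "dietz_r"` ranks the off-diagonal entries of each
#' matrix first (a rank-based statistic less sensitive to extreme values).
#' Two-sided p by default; one-sided tails also reported.
#'
#' @param mA,mB matched `association_matrix` objects or plain symmetric
#'   matrices of equal dimension.
#' @param kind `"mantel_z"` or `"dietz_r"`.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param two_sided use the two-sided p as `p` (default TRUE).
#' @return An object of class `mantel_result`: list with `kind`,
#'   `correlation`, `p`, `p_upper`, `p_lower`, `n_perm`, `n_individuals`.
#' @export
mantel_test <- function(mA, mB, kind = c("mantel_z", "dietz_r"),
                        n_perm = 10000, seed = 1L, two_sided = TRUE) {
  kind <- match.arg(kind)
  A <- if (inherits(mA, "association_matrix")) mA$sri else mA
  B <- if (inherits(mB, "association_matrix")) mB$sri else mB
  n <- nrow(A)
  stopifnot(nrow(B) == n, ncol(A) == n, ncol(B) == n)
  off <- upper.tri(A) | lower.tri(A)
  va <- A[off]
  if (sd(va) == 0 || sd(B[off]) == 0) {
    stop_named("mA/mB", "constant matrix: correlation undefined")
  }
  rank_mat <- function(m) {
    r <- m
    r[off] <- rank(m[off])
    r
  }
  if (kind == "dietz_r") {
    A <- rank_mat(A)
    B <- rank_mat(B)
    va <- A[off]
  }
  obs <- cor(va, B[off])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(va, B[p, p][off])
  }, 0))
  p_upper <- (1 + sum(null >= obs)) / (1 + n_perm)
  p_lower <- (1 + sum(null <= obs)) / (1 + n_perm)
  p_two <- min(1, 2 * min(p_upper, p_lower))
  structure(list(kind = kind, correlation = obs,
                 p = if (two_sided) p_two else p_upper,
                 p_upper = p_upper, p_lower = p_lower,
                 n_perm = n_perm, n_individuals = n),
            class = "mantel_result")
}

#' Repeated-run Mantel test
#'
#' Convenience wrapper reproducing the "k runs of n permutations, mean p and
#' correlation" reporting convention. The single-run add-one p of
#' [mantel_test()] is statistically cleaner and remains the default
#' elsewhere.
#'
#' @inheritParams mantel_test
#' @param runs number of repeated runs (default 3).
#' @return list with `mean_correlation`, `mean_p`, `sd_p`, `runs`.
#' @export
mantel_repeated <- function(mA, mB, kind = c("mantel_z", "dietz_r"),
                            n_perm = 10000, runs = 3, seed = 1L,
                            two_sided = TRUE) {
  kind <- match.arg(kind)
  res <- lapply(seq_len(runs), function(k) {
    mantel_test(mA, mB, kind, n_perm, seed = seed + k - 1L, two_sided)
  })
  ps <- vapply(res, `[[`, 0, "p")
  list(mean_correlation = mean(vapply(res, `[[`, 0, "correlation")),
       mean_p = mean(ps), sd_p = sd(ps), runs = runs)
}

#' Fisher's omnibus combination of independent p-values
#'
#' `chi2 = -2 * sum(log(p))` follows a chi-square distribution with `2k`
#' degrees of freedom under the joint null. The statistic is additive:
#' combining the chi-squares (and dfs) of disjoint p-value sets equals
#' combining all p-values at once. Zero p-values are rejected - permutation
#' p-values must use the add-one convention upstream.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return list with `chi2`, `df`, `p`.
#' @export
fisher_omnibus <- function(pvalues) {
  if (length(pvalues) == 0) stop_named("pvalues", "empty")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop_named("pvalues", "all p-values must be in (0, 1]")
  }
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Seasonal stability of association patterns within territories
#'
#' Tests every within-territory pair of seasonal association matrices with
#' both Mantel statistics, groups the results by the time difference between
#' the compared seasons (1 = consecutive, 2 = one season apart, 3 = two
#' apart), and combines the Dietz-R p-values per territory per time
#' difference - and across territories ("All") - with Fisher's omnibus test.
#'
#' @param networks named list of territories, each a named chronological list
#'   of `association_matrix` objects (one per season).
#' @param n_perm permutations per Mantel test.
#' @param seed integer seed.
#' @param min_shared minimum shared individuals for a pair to be testable.
#' @param two_sided passed to [mantel_test()].
#' @return list with `pairs` (per-pair test results) and `combined`
#'   (territory x time-difference omnibus table, including the "All" rows).
#' @export
seasonal_stability_report <- function(networks, n_perm = 10000, seed = 1L,
                                      min_shared = 3, two_sided = TRUE) {
  pair_rows <- list()
  for (terr in names(networks)) {
    seasons <- networks[[terr]]
    ns <- length(seasons)
    if (ns < 2) next
    for (i in seq_len(ns - 1)) {
      for (j in seq((i + 1), ns)) {
        td <- j - i
        res <- tryCatch({
          mm <- match_matrices(seasons[[i]], seasons[[j]], min_shared)
          z <- mantel_test(mm$mA, mm$mB, "mantel_z", n_perm,
                           seed = seed, two_sided = two_sided)
          r <- mantel_test(mm$mA, mm$mB, "dietz_r", n_perm,
                           seed = seed + 1L, two_sided = two_sided)
          data.frame(territory = terr,
                     season_a = names(seasons)[i] %||% i,
                     season_b = names(seasons)[j] %||% j,
                     time_between = td,
                     mantel_r = z$correlation, mantel_p = z$p,
                     dietz_r = r$correlation, dietz_p = r$p,
                     n_shared = z$n_individuals,
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL)
        if (!is.null(res)) pair_rows[[length(pair_rows) + 1]] <- res
      }
    }
  }
  pairs <- do.call(rbind, pair_rows)
  combined <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    rows <- list()
    for (terr in unique(pairs$territory)) {
      for (td in sort(unique(pairs$time_between))) {
        ps <- pairs$dietz_p[pairs$territory == terr &
                              pairs$time_between == td]
        if (length(ps) == 0) next
        om <- fisher_omnibus(ps)
        rows[[length(rows) + 1]] <- data.frame(
          territory = terr, time_between = td, chi2 = om$chi2, df = om$df,
          p = om$p, n_tests = length(ps), stringsAsFactors = FALSE)
      }
    }
    for (td in sort(unique(pairs$time_between))) {
      ps <- pairs$dietz_p[pairs$time_between == td]
      om <- fisher_omnibus(ps)
      rows[[length(rows) + 1]] <- data.frame(
        territory = "All", time_between = td, chi2 = om$chi2, df = om$df,
        p = om$p, n_tests = length(ps), stringsAsFactors = FALSE)
    }
    combined <- do.call(rbind, rows)
    rownames(combined) <- NULL
  }
  list(pairs = pairs, combined = combined)
}
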