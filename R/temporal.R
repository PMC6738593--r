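# Lagged association/identification rates and exponential decay models.

# internal: day-level association edge sets and identification matrix
day_structures <- function(groups, individuals = NULL) {
  individuals <- individuals %||% sort(unique(groups$individual_id))
  n <- length(individuals)
  days <- sort(unique(groups$sampling_day))
  nd <- length(days)
  seen <- matrix(FALSE, nd, n, dimnames = list(days, individuals))
  edges <- vector("list", nd)
  idx <- match(groups$individual_id, individuals)
  didx <- match(groups$sampling_day, days)
  seen[cbind(didx, idx)] <- TRUE
  for (d in seq_len(nd)) edges[[d]] <- integer(0)
  for (g in split(data.frame(i = idx, d = didx), groups$group_id)) {
    members <- sort(unique(g$i))
    if (length(members) >= 2) {
      pr <- t(utils::combn(members, 2))
      keys <- (pr[, 1] - 1L) * n + pr[, 2]
      d <- g$d[1]
      edges[[d]] <- union(edges[[d]], keys)
    }
  }
  list(individuals = individuals, n = n, days = days, seen = seen,
       edges = edges)
}

# default lag bins: integer-day lags to 40, then logarithmically widened
default_lag_bins <- function(max_lag) {
  edges <- seq_len(min(40L, max_lag))
  if (max_lag > 40) {
    e <- 40
    while (e < max_lag) {
      e <- min(max_lag, ceiling(e * 1.3))
      edges <- c(edges, e)
    }
  }
  cbind(lo = c(1, head(edges, -1) + 1)[seq_along(edges)], hi = edges)
}

#' Lagged association rate
#'
#' The probability that a dyad associated on day `d` is associated again on
#' day `d + tau`, given both members were identified on day `d + tau`,
#' estimated as a pooled ratio of sums within each lag bin: numerator = count
#' of (dyad, day pair) events still associated, denominator = count of such
#' events with both members identified at the later day. Standard errors are
#' from the temporal jackknife (days omitted in turn). Empty bins are
#' reported with `n_pairs = 0`, not dropped.
#'
#' @param groups a group table.
#' @param bins matrix with columns `lo`, `hi` (inclusive day-lag bounds); by
#'   default integer lags to 40 days then logarithmically widened bins.
#' @param jackknife compute leave-one-day-out standard errors.
#' @return An object of class `lag_curve` (`kind = "LAR"`): data.frame with
#'   `lag_lo`, `lag_hi`, `lag_mid`, `rate`, `se`, `n_pairs` (denominator
#'   events), `num`.
#' @export
lagged_association_rate <- function(groups, bins = NULL, jackknife = TRUE) {
  st <- day_structures(groups)
  nd <- length(st$days)
  if (nd < 2) stop_named("groups", "need >= 2 sampling days")
  max_lag <- max(st$days) - min(st$days)
  bins <- bins %||% default_lag_bins(max_lag)
  nb <- nrow(bins)
  num <- den <- numeric(nb)
  num_day <- den_day <- matrix(0, nd, nb)
  for (d1 in seq_len(nd)) {
    e1 <- st$edges[[d1]]
    if (length(e1) == 0) next
    i1 <- (e1 - 1L) %/% st$n + 1L
    j1 <- (e1 - 1L) %% st$n + 1L
    for (d2 in seq_len(nd)) {
      if (d2 == d1) next
      tau <- abs(st$days[d2] - st$days[d1])
      b <- which(bins[, "lo"] <= tau & tau <= bins[, "hi"])
      if (length(b) == 0) next
      if (st$days[d2] < st$days[d1]) next
      both <- st$seen[d2, i1] & st$seen[d2, j1]
      dn <- sum(both)
      if (dn == 0) next
      nm <- length(intersect(e1[both], st$edges[[d2]]))
      num[b] <- num[b] + nm
      den[b] <- den[b] + dn
      num_day[d1, b] <- num_day[d1, b] + nm
      den_day[d1, b] <- den_day[d1, b] + dn
      num_day[d2, b] <- num_day[d2, b] + nm
      den_day[d2, b] <- den_day[d2, b] + dn
    }
  }
  rate <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  se <- rep(NA_real_, nb)
  if (jackknife && nd >= 3) {
    se <- jackknife_curve_se(num, den, num_day, den_day)
  }
  curve <- data.frame(lag_lo = bins[, "lo"], lag_hi = bins[, "hi"],
                      lag_mid = (bins[, "lo"] + bins[, "hi"]) / 2,
                      rate = rate, se = se, n_pairs = den, num = num)
  structure(curve, class = c("lag_curve", "data.frame"), kind = "LAR")
}

# jackknife SE of a ratio-of-sums curve from per-day contributions
jackknife_curve_se <- function(num, den, num_day, den_day) {
  nd <- nrow(num_day)
  nb <- length(num)
  reps <- matrix(NA_real_, nd, nb)
  for (k in seq_len(nd)) {
    dk <- den - den_day[k, ]
    reps[k, ] <- ifelse(dk > 0, (num - num_day[k, ]) / pmax(dk, 1), NA_real_)
  }
  vapply(seq_len(nb), function(b) {
    r <- reps[, b]
    r <- r[!is.na(r)]
    m <- length(r)
    if (m < 2) return(NA_real_)
    sqrt((m - 1) / m * sum((r - mean(r))^2))
  }, 0)
}

#' Null association rate
#'
#' The association rate expected if, on each day, individuals chose partners
#' at random while keeping their observed gregariousness. For individuals
#' `i, j` both seen on day `e` with `a_i(e)` distinct observed associates
#' among the `n_e` individuals seen, the null association probability is
#' `min(1, a_i a_j / ((n_e - 1) * abar_e))` with `abar_e` the mean number of
#' associates that day. This closed form is exact at saturation (everyone
#' associated with everyone: NAR = 1) and exact in expectation under
#' homogeneous independent association; against heterogeneous data it is
#' validated by the within-day partner-permutation oracle. The pooled NAR
#' averages this probability over the same (dyad, day-pair) events that
#' form the LAR denominator.
#'
#' @param groups a group table.
#' @param bins as in [lagged_association_rate()]; NULL pools all lags into
#'   one value.
#' @return if `bins` is NULL, a single pooled NAR value; otherwise a
#'   data.frame of per-bin null rates.
#' @export
null_association_rate <- function(groups, bins = NULL) {
  st <- day_structures(groups)
  nd <- length(st$days)
  if (nd < 2) stop_named("groups", "need >= 2 sampling days")
  # per-day null association probability ingredients
  amat <- matrix(0, nd, st$n) # distinct associates per (day, individual)
  for (d in seq_len(nd)) {
    e <- st$edges[[d]]
    if (length(e) == 0) next
    i <- (e - 1L) %/% st$n + 1L
    j <- (e - 1L) %% st$n + 1L
    t1 <- tabulate(i, nbins = st$n)
    t2 <- tabulate(j, nbins = st$n)
    amat[d, ] <- t1 + t2
  }
  pooled <- is.null(bins)
  if (pooled) bins <- cbind(lo = 1, hi = max(st$days) - min(st$days))
  nb <- nrow(bins)
  nullsum <- den <- numeric(nb)
  for (d1 in seq_len(nd)) {
    e1 <- st$edges[[d1]]
    if (length(e1) == 0) next
    i1 <- (e1 - 1L) %/% st$n + 1L
    j1 <- (e1 - 1L) %% st$n + 1L
    for (d2 in seq_len(nd)) {
      if (st$days[d2] <= st$days[d1]) next
      tau <- st$days[d2] - st$days[d1]
      b <- which(bins[, "lo"] <= tau & tau <= bins[, "hi"])
      if (length(b) == 0) next
      both <- st$seen[d2, i1] & st$seen[d2, j1]
      if (!any(both)) next
      n_e <- sum(st$seen[d2, ])
      abar <- mean(amat[d2, st$seen[d2, ]])
      p <- if (abar == 0 || n_e < 2) rep(0, sum(both)) else {
        pmin(1, amat[d2, i1[both]] * amat[d2, j1[both]] /
               ((n_e - 1) * abar))
      }
      nullsum[b] <- nullsum[b] + sum(p)
      den[b] <- den[b] + sum(both)
    }
  }
  rate <- ifelse(den > 0, nullsum / pmax(den, 1), NA_real_)
  if (pooled) return(rate[1])
  data.frame(lag_lo = bins[, "lo"], lag_hi = bins[, "hi"], null_rate = rate,
             n_pairs = den)
}

#' Lagged identification rate
#'
#' The probability that an individual identified in the study area on day
#' `d` is the same as a randomly chosen identified individual on day
#' `d + tau`: per lag bin, the ratio of same-individual identification pairs
#' to all identification pairs. A purely demographic baseline - a decline
#' marks emigration or mortality, not social change. For a closed population
#' of `N` individuals all detected daily, the rate is `1/N` at every lag.
#'
#' @param detections a validated detection table (or precomputed groups with
#'   `sampling_day`).
#' @param bins as in [lagged_association_rate()].
#' @param boundary_hour sampling-period boundary (default noon).
#' @param jackknife compute leave-one-day-out standard errors.
#' @return a `lag_curve` with `kind = "LIR"`.
#' @export
lagged_identification_rate <- function(detections, bins = NULL,
                                       boundary_hour = 12,
                                       jackknife = TRUE) {
  if (!is.null(detections$timestamp) && is.null(detections$sampling_day)) {
    detections$sampling_day <- assign_sampling_day(detections$timestamp,
                                                   boundary_hour)
  }
  seen_df <- unique(detections[c("individual_id", "sampling_day")])
  ids <- sort(unique(seen_df$individual_id))
  days <- sort(unique(seen_df$sampling_day))
  nd <- length(days)
  if (nd < 2) stop_named("detections", "need >= 2 sampling days")
  seen <- matrix(0, nd, length(ids), dimnames = list(days, ids))
  seen[cbind(match(seen_df$sampling_day, days),
             match(seen_df$individual_id, ids))] <- 1
  max_lag <- max(days) - min(days)
  bins <- bins %||% default_lag_bins(max_lag)
  lir_from_seen(seen, days, bins, jackknife)
}

# pooled-ratio LIR from a (day x individual) identification matrix
lir_from_seen <- function(seen, days, bins, jackknife = TRUE) {
  nd <- nrow(seen)
  nb <- nrow(bins)
  M <- tcrossprod(seen)            # same-individual identification pairs
  n_per_day <- rowSums(seen)
  P <- outer(n_per_day, n_per_day) # all identification pairs
  lagm <- outer(days, days, function(a, b) b - a)
  num <- den <- numeric(nb)
  num_day <- den_day <- matrix(0, nd, nb)
  for (b in seq_len(nb)) {
    sel <- lagm >= bins[b, "lo"] & lagm <= bins[b, "hi"]
    num[b] <- sum(M[sel])
    den[b] <- sum(P[sel])
    if (jackknife) {
      Ms <- M * sel
      Ps <- P * sel
      num_day[, b] <- rowSums(Ms) + colSums(Ms)
      den_day[, b] <- rowSums(Ps) + colSums(Ps)
    }
  }
  rate <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  se <- rep(NA_real_, nb)
  if (jackknife && nd >= 3) se <- jackknife_curve_se(num, den, num_day,
                                                     den_day)
  curve <- data.frame(lag_lo = bins[, "lo"], lag_hi = bins[, "hi"],
                      lag_mid = (bins[, "lo"] + bins[, "hi"]) / 2,
                      rate = rate, se = se, n_pairs = den, num = num)
  structure(curve, class = c("lag_curve", "data.frame"), kind = "LIR")
}

#' Bootstrap standard errors for LIR model parameters
#'
#' The per-bin pair counts of a lagged identification rate are strongly
#' dependent (the same individuals appear in every day pair), so
#' model-based standard errors understate the uncertainty of fitted
#' demographic parameters. Bootstrapping individuals - resampling whole
#' identification histories with replacement, recomputing the curve and
#' refitting - captures the demographic stochasticity that dominates.
#'
#' @param detections a validated detection table.
#' @param family the LIR family to refit (e.g. `"emig_mort"`).
#' @param n_boot bootstrap replicates (default 100).
#' @param bins optional lag bins.
#' @param boundary_hour sampling-period boundary.
#' @param seed integer seed.
#' @return list with `se` (named, natural parameters), `estimates` (replicate
#'   matrix), `n_failed`.
#' @export
lir_bootstrap_se <- function(detections, family, n_boot = 100, bins = NULL,
                             boundary_hour = 12, seed = 1L) {
  if (!is.null(detections$timestamp) && is.null(detections$sampling_day)) {
    detections$sampling_day <- assign_sampling_day(detections$timestamp,
                                                   boundary_hour)
  }
  seen_df <- unique(detections[c("individual_id", "sampling_day")])
  ids <- sort(unique(seen_df$individual_id))
  days <- sort(unique(seen_df$sampling_day))
  seen <- matrix(0, length(days), length(ids))
  seen[cbind(match(seen_df$sampling_day, days),
             match(seen_df$individual_id, ids))] <- 1
  bins <- bins %||% default_lag_bins(max(days) - min(days))
  picks <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    sample(ncol(seen), replace = TRUE)
  }))
  reps <- list()
  n_failed <- 0
  for (b in seq_len(n_boot)) {
    pick <- picks[[b]]
    curve <- lir_from_seen(seen[, pick, drop = FALSE], days, bins,
                           jackknife = FALSE)
    fit <- tryCatch(
      fit_decay_models(curve, kind = "LIR", families = family,
                       seed = seed + b),
      error = function(e) NULL)
    m <- if (is.null(fit)) NULL else fit$models[[family]]
    if (is.null(m) || isTRUE(m$failed)) {
      n_failed <- n_failed + 1
    } else {
      reps[[length(reps) + 1]] <- m$parameters$estimate
    }
  }
  est <- do.call(rbind, reps)
  list(se = apply(est, 2, sd), estimates = est, n_failed = n_failed)
}

#' Temporal jackknife standard errors for an arbitrary day-grouped estimator
#'
#' Leave-one-day-out jackknife: `SE = sqrt(((m - 1)/m) * sum((theta_i -
#' theta_bar)^2))` over the `m` leave-one-out replicates.
#'
#' @param estimator function taking a group table and returning a numeric
#'   vector.
#' @param groups a group table (needs >= 3 distinct sampling days).
#' @return numeric vector of SEs, same length as the estimator output.
#' @export
jackknife_se <- function(estimator, groups) {
  days <- sort(unique(groups$sampling_day))
  m <- length(days)
  if (m < 3) stop_named("groups", "jackknife needs >= 3 days")
  reps <- vapply(days, function(d) {
    estimator(groups[groups$sampling_day != d, , drop = FALSE])
  }, estimator(groups))
  reps <- matrix(reps, ncol = m)
  apply(reps, 1, function(r) {
    sqrt((m - 1) / m * sum((r - mean(r))^2))
  })
}
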