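# Independent brute-force oracles and fixture builders shared across tests.
# Every oracle is a direct, unoptimised restatement of a definition; none
# shares code with the implementation it checks.

# build a group table from a list of day -> list of member vectors
make_groups <- function(days_list, patch = "P1", territory = "T1") {
  rows <- list()
  gid <- 0
  for (k in seq_along(days_list)) {
    day <- as.integer(names(days_list)[k] %||% k)
    for (members in days_list[[k]]) {
      gid <- gid + 1
      rows[[gid]] <- data.frame(group_id = gid, sampling_day = day,
                                patch_id = patch, territory_id = territory,
                                individual_id = members,
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random group fixture: n individuals, nd days, random groups per day
random_groups <- function(n = 10, nd = 15, mean_groups = 4,
                          max_size = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("i%02d", seq_len(n))
  rows <- list()
  gid <- 0
  for (d in seq_len(nd)) {
    for (g in seq_len(max(1, rpois(1, mean_groups)))) {
      size <- sample(max_size, 1)
      members <- sample(ids, size)
      gid <- gid + 1
      rows[[gid]] <- data.frame(group_id = gid, sampling_day = d,
                                patch_id = sample(c("P1", "P2", "P3"), 1),
                                territory_id = "T1",
                                individual_id = members,
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# brute-force dyadic tallies: loop over every (day, dyad) and classify
oracle_tally <- function(groups, individuals) {
  n <- length(individuals)
  x <- yab <- ya <- yb <- matrix(0, n, n,
                                 dimnames = list(individuals, individuals))
  for (day in unique(groups$sampling_day)) {
    gd <- groups[groups$sampling_day == day, ]
    seen <- unique(gd$individual_id)
    assoc <- matrix(FALSE, n, n)
    for (gidv in unique(gd$group_id)) {
      mem <- match(unique(gd$individual_id[gd$group_id == gidv]),
                   individuals)
      mem <- mem[!is.na(mem)]
      if (length(mem) >= 2) assoc[mem, mem] <- TRUE
    }
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        sa <- individuals[a] %in% seen
        sb <- individuals[b] %in% seen
        if (sa && sb && assoc[a, b]) {
          x[a, b] <- x[a, b] + 1
        } else if (sa && sb) {
          yab[a, b] <- yab[a, b] + 1
        } else if (sa) {
          ya[a, b] <- ya[a, b] + 1
        } else if (sb) {
          yb[a, b] <- yb[a, b] + 1
        }
      }
    }
  }
  list(x = x, y_ab = yab, y_a = ya, y_b = yb,
       d = x + yab + ya + yb)
}

# brute-force LAR: loop over (dyad, day pair)
oracle_lar <- function(groups, individuals, max_lag) {
  days <- sort(unique(groups$sampling_day))
  seen_on <- function(id, day) {
    any(groups$individual_id == id & groups$sampling_day == day)
  }
  assoc_on <- function(a, b, day) {
    gd <- groups[groups$sampling_day == day, ]
    any(vapply(unique(gd$group_id), function(gg) {
      mem <- gd$individual_id[gd$group_id == gg]
      a %in% mem && b %in% mem
    }, TRUE))
  }
  num <- den <- rep(0, max_lag)
  pairs <- t(utils::combn(individuals, 2))
  for (d1 in days) {
    for (tau in seq_len(max_lag)) {
      d2 <- d1 + tau
      if (!(d2 %in% days)) next
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1]
        b <- pairs[r, 2]
        if (assoc_on(a, b, d1) && seen_on(a, d2) && seen_on(b, d2)) {
          den[tau] <- den[tau] + 1
          if (assoc_on(a, b, d2)) num[tau] <- num[tau] + 1
        }
      }
    }
  }
  ifelse(den > 0, num / pmax(den, 1), NA_real_)
}

# brute-force LIR: loop over day pairs, count identification pairs
oracle_lir <- function(det, max_lag) {
  days <- sort(unique(det$sampling_day))
  ids_on <- function(day) unique(det$individual_id[det$sampling_day == day])
  num <- den <- rep(0, max_lag)
  for (d1 in days) {
    for (tau in seq_len(max_lag)) {
      d2 <- d1 + tau
      if (!(d2 %in% days)) next
      a <- ids_on(d1)
      b <- ids_on(d2)
      num[tau] <- num[tau] + length(intersect(a, b))
      den[tau] <- den[tau] + length(a) * length(b)
    }
  }
  ifelse(den > 0, num / pmax(den, 1), NA_real_)
}

# all set partitions of 1..n as integer label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (lab in seq_len(k + 1)) rec(c(labels, lab), max(k, lab))
  }
  rec(integer(0), 0)
  out
}

# exhaustive maximum modularity over all partitions
oracle_max_modularity <- function(A) {
  n <- nrow(A)
  s <- rowSums(A)
  W2 <- sum(s)
  B <- A - outer(s, s) / W2
  best <- -Inf
  for (p in all_partitions(n)) {
    same <- outer(p, p, "==")
    q <- sum(B[same]) / W2
    if (q > best) best <- q
  }
  best
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# synthetic lag curve with binomial counts from a true rate function
make_curve <- function(p, den, kind = "LAR") {
  tau <- seq_along(p)
  num <- rbinom(length(p), den, p)
  structure(data.frame(lag_lo = tau, lag_hi = tau, lag_mid = tau,
                       rate = num / den, se = NA_real_, n_pairs = den,
                       num = num),
            class = c("lag_curve", "data.frame"), kind = kind)
}

# beta-binomial dyadic counts with planted mean/CV, packed as dyad_counts
make_bb_counts <- function(n_dyads, d, mu, cv, seed) {
  set.seed(seed)
  p <- if (cv == 0) rep(mu, n_dyads) else {
    s <- (1 - mu) / (mu * cv^2) - 1
    rbeta(n_dyads, mu * s, (1 - mu) * s)
  }
  x <- rbinom(n_dyads, d, p)
  n <- ceiling((1 + sqrt(1 + 8 * n_dyads)) / 2)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  pairs <- pairs[seq_len(n_dyads), , drop = FALSE]
  xm <- dm <- matrix(0, n, n)
  xm[pairs] <- x
  dm[pairs] <- d
  xm <- xm + t(xm)
  dm <- dm + t(dm)
  structure(list(individuals = paste0("i", seq_len(n)), x = xm,
                 y_ab = dm * 0, y_a = dm * 0, y_b = dm * 0, d = dm,
                 n_days = d),
            class = "dyad_counts")
}

# association_matrix wrapper around a plain symmetric matrix
as_assoc <- function(A, mask = NULL) {
  n <- nrow(A)
  ids <- colnames(A) %||% paste0("i", seq_len(n))
  structure(list(individuals = ids, sri = A,
                 d = (A * 0) + 1 - diag(n),
                 mask = mask %||% (diag(n) == 1)),
            class = "association_matrix")
}
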