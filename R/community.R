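# Community detection on association matrices with a gregariousness-
# preserving (weighted configuration) null model.

#' Weighted modularity of a partition
#'
#' `Q = (1/2W) * sum_ij (A_ij - s_i s_j / 2W) delta(c_i, c_j)` over ordered
#' pairs `i != j`, where `A` is the SRI matrix, `s_i` its row sums and `2W`
#' the total weight. The expected-weight term `s_i s_j / 2W` is the weighted
#' configuration null, which controls for individual differences in
#' gregariousness. A single community always has `Q = 0`; `Q > 0.3` is
#' conventionally taken as a useful division.
#'
#' @param m an `association_matrix` (or plain symmetric matrix).
#' @param labels community labels, one per individual (vector, any type).
#' @return the modularity Q.
#' @export
modularity_q <- function(m, labels) {
  A <- if (inherits(m, "association_matrix")) m$sri else m
  n <- nrow(A)
  if (n == 0) stop_named("m", "empty matrix")
  if (length(labels) != n) stop_named("labels", "must cover all individuals")
  diag(A) <- 0
  s <- rowSums(A)
  W2 <- sum(s)
  if (W2 == 0) return(0)
  # the null term keeps its diagonal (self-pair expectation), as in the
  # standard weighted-modularity definition, so one community gives Q = 0
  same <- outer(labels, labels, "==")
  B <- A - outer(s, s) / W2
  sum(B[same]) / W2
}

#' Leading-eigenvector community detection
#'
#' Recursive spectral bisection of the weighted modularity matrix: each
#' candidate group is split by the sign of the leading eigenvector of its
#' generalised modularity matrix, refined by Kernighan-Lin single-vertex
#' moves, and the split is kept only if it increases Q. Individuals with no
#' unmasked positive association (isolates in the weighted graph) are
#' labelled `"unassigned"` and excluded from the optimisation. If the final
#' maximised Q is below `q_threshold` (default 0.3) the division is not
#' considered useful and all assigned individuals are returned as one
#' community.
#'
#' @param m an `association_matrix`.
#' @param q_threshold minimum useful modularity (default 0.3).
#' @param kl Kernighan-Lin refinement after each bisection (default TRUE).
#' @return An object of class `sna_partition`: list with `labels` (named
#'   character vector; `"unassigned"` for isolates), `Q` (modularity of the
#'   returned division over assigned individuals), `method`,
#'   `n_communities`.
#' @export
eigenvector_communities <- function(m, q_threshold = 0.3, kl = TRUE) {
  A <- m$sri
  A[m$mask] <- 0
  diag(A) <- 0
  ids <- m$individuals
  deg <- rowSums(A)
  assigned <- which(deg > 0)
  labels <- setNames(rep("unassigned", length(ids)), ids)
  if (length(assigned) < 2) {
    return(new_partition(labels, 0, "eigenvector"))
  }
  Asub <- A[assigned, assigned, drop = FALSE]
  member <- leading_eigen_partition(Asub, kl = kl)
  Qsub <- modularity_q(Asub, member)
  if (Qsub < q_threshold) {
    member <- rep(1L, length(assigned))
    Qsub <- 0
  }
  labels[assigned] <- paste0("C", member)
  new_partition(labels, Qsub, "eigenvector")
}

new_partition <- function(labels, Q, method) {
  comms <- setdiff(unique(labels), "unassigned")
  structure(list(labels = labels, Q = Q, method = method,
                 n_communities = length(comms)),
            class = "sna_partition")
}

#' @export
print.sna_partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d communities, Q = %.3f\n",
              x$method, x$n_communities, x$Q))
  invisible(x)
}

# recursive bisection over the (global) modularity matrix; returns integer
# membership. Operates on connected components separately.
leading_eigen_partition <- function(A, kl = TRUE) {
  n <- nrow(A)
  s <- rowSums(A)
  W2 <- sum(s)
  B <- A - outer(s, s) / W2
  member <- integer(n)
  next_label <- 0L

  comp <- graph_components(A)
  for (cid in unique(comp)) {
    verts <- which(comp == cid)
    next_label <- next_label + 1L
    member[verts] <- next_label
    queue <- list(verts)
    while (length(queue) > 0) {
      g <- queue[[1]]
      queue <- queue[-1]
      if (length(g) < 2) next
      # generalised modularity matrix for subdivision of group g
      Bg <- B[g, g, drop = FALSE]
      diag(Bg) <- diag(Bg) - rowSums(B[g, g, drop = FALSE])
      ev <- eigen(Bg, symmetric = TRUE)
      v <- ev$vectors[, 1]
      if (ev$values[1] <= 1e-12) next
      side <- v >= 0
      if (all(side) || !any(side)) next
      if (kl) side <- kl_refine(Bg, side)
      if (all(side) || !any(side)) next
      dq <- kl_gain_total(Bg, side)
      if (dq <= 1e-12) next
      g1 <- g[side]
      g2 <- g[!side]
      next_label <- next_label + 1L
      member[g2] <- next_label
      queue <- c(queue, list(g1), list(g2))
    }
  }
  # global Kernighan-Lin stage: greedy single-vertex moves between
  # communities (or to a new singleton) and community merges, run from the
  # bisection result and from an all-singletons start, keeping the better
  # division; recursive bisection alone can stall short of the optimum on
  # weakly structured graphs
  if (kl) {
    s <- rowSums(A)
    W2 <- sum(s)
    B <- A - outer(s, s) / W2
    starts <- list(member, seq_along(member))
    if (n <= 20) {
      # near-degenerate small instances profit from a few randomised
      # starts; the internal seed keeps the partitioner deterministic
      starts <- c(starts, with_seed(181201, lapply(1:20, function(r) {
        sample(3, n, replace = TRUE)
      })))
    }
    best_q <- -Inf
    for (st in starts) {
      cand <- refine_partition(B, W2, st)
      q <- sum(B[outer(cand, cand, "==")]) / W2
      if (q > best_q + 1e-12) {
        best_q <- q
        member <- cand
      }
    }
  }
  match(member, sort(unique(member)))
}

# greedy Q maximisation by single-vertex moves and community merges, using
# incremental modularity deltas on the precomputed modularity matrix B
refine_partition <- function(B, W2, member) {
  n <- length(member)
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      comms <- unique(member)
      # gain of moving v into community c: 2 * sum(B[v, c]) / W2 (self term
      # B_vv constant); leaving its own community loses its current ties
      ties <- vapply(comms, function(cm) {
        sum(B[v, member == cm]) - B[v, v] * (member[v] == cm)
      }, 0)
      names(ties) <- comms
      cur <- as.character(member[v])
      gain <- ties - ties[cur]
      # moving to a new singleton community drops all ties
      gain_single <- -ties[cur]
      best <- which.max(gain)
      if (gain[best] > 1e-12 && gain[best] >= gain_single) {
        member[v] <- comms[best]
        improved <- TRUE
      } else if (gain_single > 1e-12) {
        member[v] <- max(member) + 1L
        improved <- TRUE
      }
    }
    comms <- unique(member)
    if (length(comms) > 1) {
      for (a in seq_along(comms)) {
        for (b in seq_along(comms)) {
          if (a >= b) next
          ia <- member == comms[a]
          ib <- member == comms[b]
          if (!any(ia) || !any(ib)) next
          if (2 * sum(B[ia, ib]) > 1e-12) {
            member[ib] <- comms[a]
            improved <- TRUE
          }
        }
      }
    }
    # pairwise membership exchanges (the classic Kernighan-Lin move),
    # which escape optima that single-vertex moves cannot
    if (!improved) {
      for (v in seq_len(n - 1)) {
        for (w in (v + 1):n) {
          if (member[v] == member[w]) next
          # swap gain: v gains w's community ties and vice versa; the
          # (v, w) tie itself stays cross-community
          in_w <- member == member[w]
          in_v <- member == member[v]
          gain <- (sum(B[v, in_w]) - B[v, w]) -
            (sum(B[v, in_v]) - B[v, v]) +
            (sum(B[w, in_v]) - B[w, v]) -
            (sum(B[w, in_w]) - B[w, w])
          if (2 * gain > 1e-12) {
            tmp <- member[v]
            member[v] <- member[w]
            member[w] <- tmp
            improved <- TRUE
          }
        }
      }
    }
    # pair relocation: two vertices move together to a new community or an
    # existing one; needed when a small community is buried across two
    # existing ones
    if (!improved) {
      qcur <- sum(B[outer(member, member, "==")])
      for (v in seq_len(n - 1)) {
        for (w in (v + 1):n) {
          targets <- c(setdiff(unique(member), c(member[v], member[w])),
                       max(member) + 1L)
          for (tg in targets) {
            cand <- member
            cand[c(v, w)] <- tg
            q <- sum(B[outer(cand, cand, "==")])
            if (q > qcur + 1e-12) {
              member <- cand
              qcur <- q
              improved <- TRUE
            }
          }
        }
      }
    }
    # for small graphs, relocate vertex triples as a block; larger
    # recombinations matter only in near-degenerate instances and small
    # groups, where they are cheap to test exhaustively
    if (!improved && n <= 20) {
      qcur <- sum(B[outer(member, member, "==")])
      triples <- utils::combn(n, 3)
      for (t in seq_len(ncol(triples))) {
        trio <- triples[, t]
        targets <- c(unique(member), max(member) + 1L)
        for (tg in targets) {
          if (all(member[trio] == tg)) next
          cand <- member
          cand[trio] <- tg
          q <- sum(B[outer(cand, cand, "==")])
          if (q > qcur + 1e-12) {
            member <- cand
            qcur <- q
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  member
}

# modularity contribution (unnormalised) of a bisection: s^T Bg s with
# s = +/-1; proportional gain vs the unsplit group
kl_gain_total <- function(Bg, side) {
  sgn <- ifelse(side, 1, -1)
  as.numeric(t(sgn) %*% Bg %*% sgn)
}

# Kernighan-Lin style refinement: greedily flip single vertices while the
# bisection objective improves
kl_refine <- function(Bg, side) {
  repeat {
    sgn <- ifelse(side, 1, -1)
    base <- as.numeric(t(sgn) %*% Bg %*% sgn)
    # flipping vertex k changes objective by -4 * sgn_k * (Bg sgn)_k
    # (+ 4 Bg_kk); evaluate exactly
    gains <- vapply(seq_along(side), function(k) {
      s2 <- sgn
      s2[k] <- -s2[k]
      as.numeric(t(s2) %*% Bg %*% s2) - base
    }, 0)
    best <- which.max(gains)
    if (gains[best] <= 1e-12) break
    cand <- side
    cand[best] <- !cand[best]
    if (all(cand) || !any(cand)) break
    side <- cand
  }
  side
}

graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0) next
    cid <- cid + 1L
    stack <- start
    comp[start] <- cid
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nbr <- which(A[v, ] > 0 & comp == 0)
      comp[nbr] <- cid
      stack <- c(stack, nbr)
    }
  }
  comp
}

#' Average-linkage community detection
#'
#' Agglomerative hierarchical clustering with average linkage on
#' dissimilarity `max(SRI) - SRI`, assuming communities are nested; the
#' dendrogram is cut at every level and the cut maximising the weighted
#' modularity Q defines the communities. The same `Q < q_threshold` collapse
#' rule and isolate handling as [eigenvector_communities()] apply.
#'
#' @inheritParams eigenvector_communities
#' @return an `sna_partition` with `method = "average_linkage"`.
#' @export
average_linkage_communities <- function(m, q_threshold = 0.3) {
  A <- m$sri
  A[m$mask] <- 0
  diag(A) <- 0
  ids <- m$individuals
  deg <- rowSums(A)
  assigned <- which(deg > 0)
  labels <- setNames(rep("unassigned", length(ids)), ids)
  if (length(assigned) < 2) return(new_partition(labels, 0, "average_linkage"))
  Asub <- A[assigned, assigned, drop = FALSE]
  diss <- max(Asub) - Asub
  diag(diss) <- 0
  hc <- hclust(as.dist(diss), method = "average")
  best_q <- -Inf
  best_member <- rep(1L, length(assigned))
  for (k in seq_len(length(assigned))) {
    member <- cutree(hc, k = k)
    q <- modularity_q(Asub, member)
    if (q > best_q) {
      best_q <- q
      best_member <- member
    }
  }
  if (best_q < q_threshold) {
    best_member <- rep(1L, length(assigned))
    best_q <- 0
  }
  labels[assigned] <- paste0("C", best_member)
  new_partition(labels, best_q, "average_linkage")
}

#' Run both community-detection methods and keep the better division
#'
#' Runs eigenvector and average-linkage community detection and returns the
#' partition from the method with the higher maximised modularity (ties go to
#' the eigenvector method), together with both candidates.
#'
#' @inheritParams eigenvector_communities
#' @return list with `selected`, `eigenvector`, `average_linkage`.
#' @export
detect_communities <- function(m, q_threshold = 0.3) {
  pe <- eigenvector_communities(m, q_threshold)
  pa <- average_linkage_communities(m, q_threshold)
  sel <- if (pa$Q > pe$Q) pa else pe
  list(selected = sel, eigenvector = pe, average_linkage = pa)
}

#' Mantel test of within- versus between-community association
#'
#' Correlates the SRI matrix with a within/between-community indicator
#' matrix, permuting individual labels. Associations stronger within than
#' between communities give a positive matrix correlation and a positive
#' t-value. Two p-values are reported: `p_high` is the fraction of null
#' correlations at or below the observed one (under the convention where a
#' *high* value supports within > between) and `p_conventional` the usual
#' upper-tail probability (small = significant).
#'
#' @param m an `association_matrix`.
#' @param labels community labels (named or in `m$individuals` order);
#'   `"unassigned"` individuals are dropped.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed.
#' @return list with `correlation`, `t`, `p_high`, `p_conventional`,
#'   `n_perm`.
#' @export
community_mantel <- function(m, labels, n_perm = 5000, seed = 1L) {
  if (!is.null(names(labels))) labels <- labels[m$individuals]
  keep <- labels != "unassigned" & !is.na(labels)
  lab <- labels[keep]
  if (length(unique(lab)) < 2) {
    stop_named("labels", "need >= 2 communities for a within/between test")
  }
  A <- m$sri[keep, keep, drop = FALSE]
  maskv <- upper_vec(m$mask[keep, keep, drop = FALSE])
  av <- upper_vec(A)[!maskv]
  ind_mat <- outer(lab, lab, "==")
  obs <- cor_safe(av, upper_vec(ind_mat)[!maskv])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    pl <- sample(lab)
    cor_safe(av, upper_vec(outer(pl, pl, "=="))[!maskv])
  }, 0))
  tval <- (obs - mean(null)) / max(sd(null), .Machine$double.eps)
  list(correlation = obs, t = tval,
       p_high = (1 + sum(null <= obs)) / (1 + n_perm),
       p_conventional = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}

cor_safe <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Same-day patch-use network
#'
#' Rebuilds the association matrix with association redefined as "observed in
#' the same patch on the same day, not necessarily at the same time". This
#' purely spatial relation is a superset of the spatiotemporal (shared-visit)
#' association; comparing the two separates shared space use from genuine
#' co-occurrence.
#'
#' @param visits a visit table ([cluster_visits()]).
#' @param individuals optional fixed individual set.
#' @return an `association_matrix`.
#' @export
patch_use_network <- function(visits, individuals = NULL) {
  pseudo <- visits
  pseudo$visit_id <- as.integer(factor(paste(visits$sampling_day,
                                             visits$patch_id)))
  groups <- extract_groups(pseudo)
  simple_ratio(tally_dyads(groups, individuals))
}

#' Spatial profile of communities
#'
#' Percentage of patch visits that members of each community made in each
#' territory (rows sum to 100), with the standard deviation of the
#' member-level percentages.
#'
#' @param labels community labels (named by individual).
#' @param visits a visit table.
#' @return list with `percent` (community x territory matrix, rows sum to
#'   100) and `sd` (member-level sd of the same percentages).
#' @export
spatial_profile <- function(labels, visits) {
  vis <- unique(visits[c("visit_id", "individual_id", "territory_id")])
  vis <- vis[vis$individual_id %in% names(labels), , drop = FALSE]
  vis$community <- labels[vis$individual_id]
  terrs <- sort(unique(vis$territory_id))
  comms <- sort(unique(vis$community))
  pct <- matrix(0, length(comms), length(terrs),
                dimnames = list(comms, terrs))
  sdm <- pct
  for (cm in comms) {
    sub <- vis[vis$community == cm, , drop = FALSE]
    tab <- table(factor(sub$territory_id, levels = terrs))
    pct[cm, ] <- 100 * as.numeric(tab) / sum(tab)
    per_member <- t(vapply(split(sub, sub$individual_id), function(s) {
      tm <- table(factor(s$territory_id, levels = terrs))
      100 * as.numeric(tm) / sum(tm)
    }, numeric(length(terrs))))
    sdm[cm, ] <- if (nrow(per_member) > 1) apply(per_member, 2, sd) else 0
  }
  list(percent = pct, sd = sdm)
}

#' Consistency of community assignment across seasons
#'
#' Matches communities across seasonal partitions by greedy maximum
#' membership overlap (largest overlap first; ties broken by the smaller
#' community id) and reports, per individual, the number of seasons
#' observed, the modal (matched) community and the fraction of seasons spent
#' in it, plus population summaries.
#'
#' @param partitions named list of `sna_partition` objects, one per season,
#'   in chronological order.
#' @return list with `individuals` (data.frame), `fraction_always_same`,
#'   `fraction_two_plus_same` (fraction of individuals seen in >= 2 seasons
#'   that kept one community in at least two of them), and the
#'   `matched_labels` used.
#' @export
seasonal_consistency <- function(partitions) {
  if (length(partitions) < 2) stop_named("partitions", "need >= 2 seasons")
  ref <- NULL
  matched <- list()
  next_global <- 0L
  for (s in seq_along(partitions)) {
    lab <- partitions[[s]]$labels
    lab <- lab[lab != "unassigned"]
    if (is.null(ref)) {
      glob <- setNames(paste0("G", seq_along(unique(lab))), unique(lab))
      next_global <- length(unique(lab))
    } else {
      glob <- match_communities(ref, lab)
      new <- setdiff(unique(lab), names(glob))
      if (length(new) > 0) {
        extra <- setNames(paste0("G", next_global + seq_along(new)), new)
        next_global <- next_global + length(new)
        glob <- c(glob, extra)
      }
    }
    matched[[s]] <- setNames(unname(glob[lab]), names(lab))
    ref <- matched[[s]]
  }
  names(matched) <- names(partitions)
  ids <- unique(unlist(lapply(matched, names)))
  rows <- lapply(ids, function(id) {
    comms <- unlist(lapply(matched, function(mm) mm[id]))
    comms <- comms[!is.na(comms)]
    tab <- sort(table(comms), decreasing = TRUE)
    data.frame(individual_id = id, n_seasons = length(comms),
               modal_community = names(tab)[1],
               fraction_modal = as.numeric(tab[1]) / length(comms),
               stringsAsFactors = FALSE)
  })
  indiv <- do.call(rbind, rows)
  multi <- indiv[indiv$n_seasons >= 2, , drop = FALSE]
  list(
    individuals = indiv,
    fraction_always_same = if (nrow(multi) > 0)
      mean(multi$fraction_modal == 1) else NA_real_,
    fraction_two_plus_same = if (nrow(multi) > 0)
      mean(multi$fraction_modal * multi$n_seasons >= 2) else NA_real_,
    matched_labels = matched
  )
}

# greedy maximum-overlap matching of this season's communities to the
# reference (previous season, already globally labelled)
match_communities <- function(ref, lab) {
  shared <- intersect(names(ref), names(lab))
  out <- character(0)
  if (length(shared) > 0) {
    tab <- table(lab[shared], ref[shared])
    cells <- expand.grid(cur = rownames(tab), glob = colnames(tab),
                         stringsAsFactors = FALSE)
    cells$overlap <- as.vector(tab)
    cells <- cells[cells$overlap > 0, , drop = FALSE]
    cells <- cells[order(-cells$overlap, cells$cur, cells$glob), ,
                   drop = FALSE]
    used_cur <- used_glob <- character(0)
    for (r in seq_len(nrow(cells))) {
      if (cells$cur[r] %in% used_cur || cells$glob[r] %in% used_glob) next
      out[cells$cur[r]] <- cells$glob[r]
      used_cur <- c(used_cur, cells$cur[r])
      used_glob <- c(used_glob, cells$glob[r])
    }
  }
  out
}

#' Export a partition as CSV (and optionally GraphML)
#'
#' @param partition an `sna_partition`.
#' @param m the `association_matrix` it was computed from (needed for
#'   GraphML).
#' @param path output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path, m = NULL,
                            format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(individual_id = names(partition$labels),
                     community = unname(partition$labels),
                     method = partition$method, Q = partition$Q,
                     stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    if (is.null(m)) stop_named("m", "GraphML export needs the matrix")
    g <- association_igraph(m, partition$labels)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
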