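two_cliques <- function(eps = 0) {
  A <- matrix(0, 12, 12)
  A[1:6, 1:6] <- 1
  A[7:12, 7:12] <- 1
  diag(A) <- 0
  if (eps > 0) A[6, 7] <- A[7, 6] <- eps
  colnames(A) <- rownames(A) <- paste0("i", 1:12)
  A
}

test_that("modularity matches hand values and the exhaustive maximum", {
  A <- two_cliques()
  m <- as_assoc(A)
  expect_equal(modularity_q(m, rep(1, 12)), 0)
  expect_equal(modularity_q(m, rep(c(1, 2), each = 6)), 0.5)

  # best split of random small matrices equals brute-force search
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(5:6, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- round(runif(n * (n - 1) / 2), 2) *
      (runif(n * (n - 1) / 2) < 0.7)
    A <- A + t(A)
    if (sum(A) == 0) next
    q_star <- oracle_max_modularity(A)
    part <- foxsna:::leading_eigen_partition(A)
    expect_lte(modularity_q(A, part), q_star + 1e-9)
  }
})

test_that("leading-eigenvector detection recovers planted cliques", {
  m <- as_assoc(two_cliques(eps = 0.05))
  p <- eigenvector_communities(m)
  expect_equal(p$n_communities, 2)
  expect_equal(length(unique(p$labels[1:6])), 1)
  expect_equal(length(unique(p$labels[7:12])), 1)
  expect_false(p$labels[1] == p$labels[7])
  q_star <- 0.5 # two equal cliques, one weak bridge: split by clique
  expect_gt(p$Q, 0.4)

  # uniform complete graph collapses to one community via the Q < 0.3 rule
  U <- matrix(0.5, 10, 10)
  diag(U) <- 0
  pu <- eigenvector_communities(as_assoc(U))
  expect_equal(pu$n_communities, 1)
  expect_equal(pu$Q, 0)
})

test_that("partitions are invariant to individual ordering up to relabelling", {
  g <- random_groups(n = 12, nd = 15, seed = 12)
  m <- simple_ratio(tally_dyads(g))
  p1 <- eigenvector_communities(m, q_threshold = 0)
  perm <- sample(length(m$individuals))
  m2 <- structure(list(individuals = m$individuals[perm],
                       sri = m$sri[perm, perm], d = m$d[perm, perm],
                       mask = m$mask[perm, perm]),
                  class = "association_matrix")
  p2 <- eigenvector_communities(m2, q_threshold = 0)
  ids <- m$individuals
  co1 <- outer(p1$labels[ids], p1$labels[ids], "==")
  co2 <- outer(p2$labels[ids], p2$labels[ids], "==")
  expect_equal(co1, co2)
})

test_that("average linkage cuts the dendrogram at the exhaustive-Q level", {
  m <- as_assoc(two_cliques(eps = 0.05))
  pa <- average_linkage_communities(m)
  pe <- eigenvector_communities(m)
  # separable case: both methods find the same division
  co_a <- outer(pa$labels, pa$labels, "==")
  co_e <- outer(pe$labels, pe$labels, "==")
  expect_equal(co_a, co_e)

  # the chosen cut maximises Q across all dendrogram levels
  g <- random_groups(n = 10, nd = 12, seed = 13)
  m2 <- simple_ratio(tally_dyads(g))
  pa2 <- average_linkage_communities(m2, q_threshold = 0)
  A <- m2$sri
  A[m2$mask] <- 0
  diag(A) <- 0
  keep <- which(rowSums(A) > 0)
  As <- A[keep, keep]
  diss <- max(As) - As
  diag(diss) <- 0
  hc <- hclust(as.dist(diss), method = "average")
  q_levels <- vapply(seq_along(keep), function(k) {
    modularity_q(As, cutree(hc, k = k))
  }, 0)
  expect_equal(pa2$Q, max(max(q_levels), 0))
})

test_that("the method with the higher modularity is selected", {
  g <- random_groups(n = 14, nd = 15, seed = 14)
  m <- simple_ratio(tally_dyads(g))
  both <- detect_communities(m, q_threshold = 0)
  expect_equal(both$selected$Q,
               max(both$eigenvector$Q, both$average_linkage$Q))
})

test_that("isolates are labelled unassigned, matching a trivial partition", {
  A <- two_cliques(eps = 0.05)
  A <- rbind(cbind(A, 0), 0) # an isolate with no edges
  colnames(A) <- rownames(A) <- paste0("i", 1:13)
  p <- eigenvector_communities(as_assoc(A))
  expect_equal(unname(p$labels["i13"]), "unassigned")
  expect_equal(p$n_communities, 2)
})

test_that("within/between Mantel diagnostics behave at the extremes", {
  A <- two_cliques()
  m <- as_assoc(A)
  labels <- setNames(rep(c("a", "b"), each = 6), colnames(A))
  res <- community_mantel(m, labels, n_perm = 300, seed = 1)
  expect_gt(res$correlation, 0.9)
  expect_gt(res$t, 2)
  expect_gt(res$p_high, 0.99)  # high-p convention: within > between
  expect_lt(res$p_conventional, 0.01)

  # maximally mismatched labels flip the correlation sign
  bad <- setNames(rep(c("a", "b"), 6), colnames(A))
  res_bad <- community_mantel(m, bad, n_perm = 300, seed = 1)
  expect_lt(res_bad$correlation, 0)

  expect_error(community_mantel(m, setNames(rep("a", 12), colnames(A))),
               "communities")
})

test_that("same-day patch use is a superset of spatiotemporal association", {
  base <- as.POSIXct("2013-07-01 00:00:00", tz = "UTC")
  det <- data.frame(
    individual_id = c("A", "B"),
    timestamp = c(base + 21 * 3600, base + 26 * 3600), # 21:00 and 02:00
    patch_id = "P1", territory_id = "T1",
    sex = "unknown", status = "unknown", age_class = "unknown",
    stringsAsFactors = FALSE
  )
  v <- cluster_visits(det, gap_minutes = 10)
  expect_equal(length(unique(v$sampling_day)), 1) # same noon-to-noon day
  st <- simple_ratio(tally_dyads(extract_groups(v)))
  pu <- patch_use_network(v)
  expect_equal(st$sri["A", "B"], 0)   # not at the same time
  expect_equal(pu$sri["A", "B"], 1)   # same patch, same day

  sim <- scenario("planted_communities", seed = 4)
  vv <- cluster_visits(sim$detections)
  ids <- sort(unique(vv$individual_id))
  x_st <- tally_dyads(extract_groups(vv), ids)$x
  pseudo <- vv
  pseudo$visit_id <- as.integer(factor(paste(vv$sampling_day, vv$patch_id)))
  x_pd <- tally_dyads(extract_groups(pseudo), ids)$x
  expect_true(all(x_st <= x_pd))

})

test_that("spatial profiles sum to 100 and match brute-force counting", {
  sim <- scenario("planted_communities", seed = 5)
  v <- cluster_visits(sim$detections)
  labels <- sim$truth$community_of
  prof <- spatial_profile(labels, v)
  expect_true(all(abs(rowSums(prof$percent) - 100) < 1e-9))
  # community of territory 1 residents spends most visits in territory 1
  expect_gt(prof$percent["T1", "T1"], 50)

  # brute-force oracle on one community
  vis <- unique(v[c("visit_id", "individual_id", "territory_id")])
  vis <- vis[labels[vis$individual_id] == "T2", ]
  oracle <- 100 * table(factor(vis$territory_id,
                               levels = colnames(prof$percent))) / nrow(vis)
  expect_equal(as.numeric(prof$percent["T2", ]), as.numeric(oracle))

  # a community observed in a single territory profiles at 100%
  g1 <- make_groups(list(`1` = list(c("A", "B"))))
  v1 <- data.frame(visit_id = 1, sampling_day = 1, patch_id = "P1",
                   territory_id = "T9", individual_id = c("A", "B"))
  p1 <- spatial_profile(setNames(c("c1", "c1"), c("A", "B")), v1)
  expect_equal(unname(p1$percent["c1", "T9"]), 100)
})

test_that("seasonal consistency fractions match hand tallies", {
  mk_part <- function(labs) {
    structure(list(labels = labs, Q = 0.5, method = "eigenvector",
                   n_communities = length(setdiff(unique(labs),
                                                  "unassigned"))),
              class = "sna_partition")
  }
  ids <- c("A", "B", "C", "D")
  p1 <- mk_part(setNames(c("C1", "C1", "C2", "C2"), ids))
  same <- seasonal_consistency(list(s1 = p1, s2 = p1, s3 = p1, s4 = p1))
  expect_true(all(same$individuals$fraction_modal == 1))
  expect_equal(same$fraction_always_same, 1)

  # one individual switches once in four seasons: its fraction is 0.75
  p2 <- mk_part(setNames(c("C1", "C1", "C2", "C1"), ids)) # D switches
  res <- seasonal_consistency(list(s1 = p1, s2 = p1, s3 = p2, s4 = p1))
  frac <- res$individuals$fraction_modal[res$individuals$individual_id == "D"]
  expect_equal(frac, 0.75)
  expect_equal(res$fraction_always_same, 0.75)
  expect_equal(res$fraction_two_plus_same, 1)

  # brute-force population tally on a random fixture
  set.seed(3)
  parts <- lapply(1:3, function(s) {
    mk_part(setNames(sample(c("C1", "C2"), 5, replace = TRUE),
                     c("A", "B", "C", "D", "E")))
  })
  names(parts) <- paste0("s", 1:3)
  res2 <- seasonal_consistency(parts)
  lab_mat <- do.call(cbind, res2$matched_labels)
  oracle_always <- mean(apply(lab_mat, 1, function(r) {
    r <- r[!is.na(r)]
    length(unique(r)) == 1
  }))
  expect_equal(res2$fraction_always_same, oracle_always)
})
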