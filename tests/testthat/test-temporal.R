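test_that("permanently associated dyads hold a lagged association rate of one", {
  g <- make_groups(lapply(setNames(1:10, 1:10), function(d) {
    list(c("A", "B"), c("C", "D"))
  }))
  lar <- lagged_association_rate(g, jackknife = FALSE)
  expect_true(all(lar$rate[lar$n_pairs > 0] == 1))
  expect_true(all(diff(lar$lag_lo) > 0))
})

test_that("LAR equals the brute-force (dyad, day, lag) loop on a fixture", {
  g <- random_groups(n = 10, nd = 8, seed = 17)
  lar <- lagged_association_rate(g, bins = cbind(lo = 1:7, hi = 1:7),
                                 jackknife = FALSE)
  oracle <- oracle_lar(g, sort(unique(g$individual_id)), 7)
  expect_equal(lar$rate, oracle)
})

test_that("empty lag bins are reported, not dropped", {
  g <- make_groups(list(`1` = list(c("A", "B")), `5` = list(c("A", "B"))))
  lar <- lagged_association_rate(g, bins = cbind(lo = 1:4, hi = 1:4),
                                 jackknife = FALSE)
  expect_equal(nrow(lar), 4)
  expect_equal(lar$n_pairs[1:3], c(0, 0, 0))
  expect_equal(lar$n_pairs[4], 1)
})

test_that("NAR is exact at saturation and under homogeneous association", {
  # everyone associates with everyone daily
  g <- make_groups(lapply(setNames(1:6, 1:6), function(d) {
    list(c("A", "B", "C", "D"))
  }))
  expect_equal(null_association_rate(g), 1)

  # independent constant-probability association: LAR tracks NAR
  sim <- scenario("random_association", seed = 19)
  gg <- extract_groups(cluster_visits(sim$detections))
  lar <- lagged_association_rate(gg, jackknife = FALSE)
  nar <- null_association_rate(gg)
  pooled_lar <- sum(lar$num) / sum(lar$n_pairs)
  se <- sqrt(pooled_lar * (1 - pooled_lar) / sum(lar$n_pairs))
  # 3 Monte-Carlo SEs plus slack for the effective dependence of pair-days
  expect_lt(abs(pooled_lar - nar), max(3 * se, 0.03))
})

test_that("NAR closed form agrees with a partner-permutation oracle", {
  g <- extract_groups(cluster_visits(
    scenario("gregarious_unselective", seed = 23)$detections))
  nar <- null_association_rate(g)
  # oracle: Monte-Carlo expectation of the LAR after re-wiring each day's
  # association records at random while preserving daily partner counts
  st <- foxsna:::day_structures(g)
  set.seed(1)
  rewire_day <- function(e, n) {
    if (length(e) < 2) return(e)
    i <- (e - 1L) %/% n + 1L
    j <- (e - 1L) %% n + 1L
    stubs <- c(rbind(i, j))
    for (try in 1:200) {
      s <- sample(stubs)
      a <- pmin(s[c(TRUE, FALSE)], s[c(FALSE, TRUE)])
      b <- pmax(s[c(TRUE, FALSE)], s[c(FALSE, TRUE)])
      if (any(a == b) || anyDuplicated(paste(a, b))) next
      return((a - 1L) * n + b)
    }
    e
  }
  mc <- replicate(30, {
    edges2 <- lapply(st$edges, rewire_day, n = st$n)
    num <- den <- 0
    for (d1 in seq_along(st$days)) {
      e1 <- st$edges[[d1]]
      if (length(e1) == 0) next
      i1 <- (e1 - 1L) %/% st$n + 1L
      j1 <- (e1 - 1L) %% st$n + 1L
      for (d2 in seq_along(st$days)) {
        if (st$days[d2] <= st$days[d1]) next
        both <- st$seen[d2, i1] & st$seen[d2, j1]
        den <- den + sum(both)
        num <- num + length(intersect(e1[both], edges2[[d2]]))
      }
    }
    num / den
  })
  expect_lt(abs(nar - mean(mc)), 2 * sd(mc) + 0.01)
})

test_that("planted preferences push the LAR above the NAR at short lags", {
  g <- extract_groups(cluster_visits(
    scenario("preferred_companions", seed = 29)$detections))
  lar <- lagged_association_rate(g, jackknife = FALSE)
  nar <- null_association_rate(g)
  expect_gt(lar$rate[1], nar)
})

test_that("LIR is 1/N for a closed, fully detected population", {
  det <- expand.grid(individual_id = paste0("i", 1:8), sampling_day = 1:12,
                     stringsAsFactors = FALSE)
  lir <- lagged_identification_rate(det, jackknife = FALSE)
  expect_true(all(abs(lir$rate[lir$n_pairs > 0] - 1 / 8) < 1e-12))
})

test_that("LIR equals brute-force pair counting on a sparse fixture", {
  set.seed(31)
  det <- data.frame(
    individual_id = sample(paste0("i", 1:10), 60, replace = TRUE),
    sampling_day = sample(1:9, 60, replace = TRUE)
  )
  lir <- lagged_identification_rate(det, bins = cbind(lo = 1:8, hi = 1:8),
                                    jackknife = FALSE)
  expect_equal(lir$rate, oracle_lir(det, 8))
})

test_that("lag curves are invariant to individual relabelling", {
  g <- random_groups(n = 8, nd = 10, seed = 37)
  relab <- setNames(paste0("z", sample(8)), sort(unique(g$individual_id)))
  g2 <- g
  g2$individual_id <- unname(relab[g$individual_id])
  b <- cbind(lo = 1:9, hi = 1:9)
  expect_equal(lagged_association_rate(g, b, jackknife = FALSE)$rate,
               lagged_association_rate(g2, b, jackknife = FALSE)$rate)
  expect_equal(
    lagged_identification_rate(g[c("individual_id", "sampling_day")], b,
                               jackknife = FALSE)$rate,
    lagged_identification_rate(g2[c("individual_id", "sampling_day")], b,
                               jackknife = FALSE)$rate)
})

test_that("temporal jackknife reduces to s/sqrt(n) for a daily mean", {
  g <- random_groups(n = 6, nd = 9, seed = 41)
  per_day_stat <- function(gg) {
    vapply(split(gg, gg$sampling_day),
           function(d) length(unique(d$individual_id)), 0)
  }
  daily <- per_day_stat(g)
  est_mean <- function(gg) mean(per_day_stat(gg))
  se <- jackknife_se(est_mean, g)
  expect_equal(se, sd(daily) / sqrt(length(daily)), tolerance = 1e-10)
  # deterministic
  expect_identical(se, jackknife_se(est_mean, g))
})

test_that("jackknife curve SEs shrink with survey length", {
  cfg <- function(len) {
    sim_config(n_territories = 1, patches_per_territory = 8,
               n_subordinates_per_sex = 4,
               seasons = data.frame(label = "s1", start_day = 0,
                                    length_days = len),
               visit_rate = 1, within_community_assoc = 0.15,
               between_community_assoc = 0, gregariousness_sd = 0,
               dyad_cv = 0, dispersal_hazard = 0, mortality_hazard = 0,
               seed = 43)
  }
  b <- cbind(lo = 1:5, hi = 1:5)
  se_short <- lagged_association_rate(
    extract_groups(cluster_visits(simulate_population(cfg(25))$detections)),
    b)$se
  se_long <- lagged_association_rate(
    extract_groups(cluster_visits(simulate_population(cfg(100))$detections)),
    b)$se
  expect_lt(mean(se_long), mean(se_short))
})

test_that("decay fits recover a single exponential within two SEs", {
  set.seed(47)
  curve <- make_curve(0.5 * exp(-(1:100) / 20), 500)
  fits <- fit_decay_models(curve, seed = 1)
  m <- fits$models[["exponential"]]
  est <- m$parameters$estimate
  se <- m$parameters$se
  expect_lt(abs(est["lambda1"] - 0.05), 2 * se["lambda1"])
  expect_lt(abs(est["a1"] - 0.5), 2 * se["a1"])
  expect_true(fits$best %in% c("exponential", "exp_const", "two_exp"))
})

test_that("constant-truth curves select the constant family", {
  set.seed(53)
  wins <- replicate(8, {
    fit_decay_models(make_curve(rep(0.3, 80), 400), seed = 1)$best
  })
  expect_gte(mean(wins == "constant"), 0.75)
})

test_that("QAIC ranking reports near-ties and failed fits honestly", {
  set.seed(59)
  curve <- make_curve(0.4 * exp(-(1:60) / 15), 300)
  fits <- fit_decay_models(curve, seed = 2)
  qaics <- vapply(fits$models, function(m) m$QAIC, 0)
  expect_true(all(diff(qaics) >= -1e-9))
  expect_equal(fits$models[[1]]$dQAIC, 0)
  expect_type(fits$top_two_close, "logical")
  tab <- decay_table(fits)
  expect_true(all(c("family", "parameter", "estimate", "se", "QAIC",
                    "dQAIC") %in% names(tab)))
})

test_that("LIR families express the closed-population limit", {
  det <- expand.grid(individual_id = paste0("i", 1:10), sampling_day = 1:30,
                     stringsAsFactors = FALSE)
  lir <- lagged_identification_rate(det, jackknife = FALSE)
  fits <- fit_decay_models(lir, seed = 3)
  expect_equal(fits$best, "closed")
  n_est <- fits$models[["closed"]]$parameters$estimate["N"]
  expect_lt(abs(n_est - 10), 0.2)
})
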