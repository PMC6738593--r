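random_sym <- function(n, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- runif(n * (n - 1) / 2)
  A <- A + t(A)
  colnames(A) <- rownames(A) <- paste0("i", seq_len(n))
  A
}

test_that("matrix matching restricts to the shared roster", {
  A <- as_assoc(random_sym(6, 1))
  B <- as_assoc(random_sym(6, 2))
  mm <- match_matrices(A, B)
  expect_equal(mm$shared, A$individuals)
  expect_identical(mm$mA$sri, A$sri)

  B2 <- B
  B2$individuals <- paste0("j", 1:6)
  colnames(B2$sri) <- rownames(B2$sri) <- B2$individuals
  expect_error(match_matrices(A, B2), "shared")

  # brute-force set intersection on a partial overlap
  B3 <- B
  B3$individuals <- c("i3", "i4", "i5", "i6", "x1", "x2")
  colnames(B3$sri) <- rownames(B3$sri) <- B3$individuals
  mm3 <- match_matrices(A, B3)
  expect_setequal(mm3$shared, intersect(A$individuals, B3$individuals))
  expect_equal(mm3$mA$sri, A$sri[mm3$shared, mm3$shared])
})

test_that("Mantel statistics hit the identity and invariance cases", {
  A <- random_sym(8, 3)
  res <- mantel_test(A, A, "mantel_z", n_perm = 500, seed = 1,
                     two_sided = FALSE)
  expect_equal(res$correlation, 1)
  expect_equal(res$p, 1 / 501)

  # Dietz R is invariant under monotone transforms of either matrix
  B <- random_sym(8, 4)
  r1 <- mantel_test(A, B, "dietz_r", n_perm = 300, seed = 2)
  r2 <- mantel_test(A^3, B, "dietz_r", n_perm = 300, seed = 2)
  r3 <- mantel_test(A, exp(B), "dietz_r", n_perm = 300, seed = 2)
  expect_equal(r1$correlation, r2$correlation)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$correlation, r3$correlation)

  # naive double-loop reference for the Dietz statistic
  off <- upper.tri(A) | lower.tri(A)
  ra <- A; ra[off] <- rank(A[off])
  rb <- B; rb[off] <- rank(B[off])
  expect_equal(r1$correlation, cor(ra[off], rb[off]))

  # p invariant to simultaneous identical reordering of both matrices
  p <- sample(8)
  r4 <- mantel_test(A[p, p], B[p, p], "dietz_r", n_perm = 300, seed = 2)
  expect_equal(r4$correlation, r1$correlation)

  expect_error(mantel_test(matrix(1, 4, 4), B[1:4, 1:4]), "constant")
})

test_that("independent matrices give well-spread Mantel p-values", {
  ps <- vapply(1:30, function(s) {
    mantel_test(random_sym(7, 100 + s), random_sym(7, 200 + s),
                n_perm = 200, seed = s)$p
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("repeated-run Mantel reporting averages correlations and p-values", {
  A <- random_sym(8, 5)
  B <- random_sym(8, 6)
  rep3 <- mantel_repeated(A, B, "dietz_r", n_perm = 200, runs = 3, seed = 1)
  expect_length(rep3$mean_p, 1)
  expect_gte(rep3$sd_p, 0)
  expect_equal(rep3$runs, 3)
})

test_that("Fisher's omnibus test matches direct computation and is additive", {
  one <- fisher_omnibus(1)
  expect_equal(one$chi2, 0)
  expect_equal(one$df, 2)
  expect_equal(one$p, 1)

  two <- fisher_omnibus(c(0.05, 0.05))
  expect_equal(two$chi2, -4 * log(0.05), tolerance = 1e-12) # 11.98
  expect_equal(two$chi2, 11.98, tolerance = 1e-3)
  expect_equal(two$df, 4)
  expect_equal(two$p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE))
  expect_equal(two$p, 0.0174, tolerance = 1e-2)

  # additivity: chi2 of a concatenated list equals the sum of the parts
  pa <- c(0.02, 0.8, 0.4)
  pb <- c(0.1, 0.6)
  whole <- fisher_omnibus(c(pa, pb))
  parts <- list(fisher_omnibus(pa), fisher_omnibus(pb))
  expect_equal(whole$chi2, parts[[1]]$chi2 + parts[[2]]$chi2)
  expect_equal(whole$df, parts[[1]]$df + parts[[2]]$df)

  expect_error(fisher_omnibus(c(0.5, 0)), "p-values")
  expect_error(fisher_omnibus(numeric(0)), "empty")
})

test_that("seasonal stability grouping follows the time-difference rule", {
  set.seed(7)
  mats <- lapply(1:4, function(k) as_assoc(random_sym(8, 300 + k)))
  names(mats) <- c("spring", "summer", "autumn", "winter")
  rep <- seasonal_stability_report(list(T1 = mats), n_perm = 200, seed = 1)
  expect_equal(sum(rep$pairs$time_between == 1), 3)
  expect_equal(sum(rep$pairs$time_between == 2), 2)
  expect_equal(sum(rep$pairs$time_between == 3), 1)
  td1 <- rep$pairs[rep$pairs$time_between == 1, c("season_a", "season_b")]
  expect_equal(paste(td1$season_a, td1$season_b),
               c("spring summer", "summer autumn", "autumn winter"))
  comb <- rep$combined
  expect_true(all(c("territory", "time_between", "chi2", "df", "p")
                  %in% names(comb)))
  # the All row sums the per-territory chi-squares at each time difference
  for (td in 1:3) {
    parts <- comb$chi2[comb$territory != "All" & comb$time_between == td]
    expect_equal(comb$chi2[comb$territory == "All" &
                             comb$time_between == td], sum(parts))
  }
})

test_that("stable association structure is detected; shuffled is not", {
  base <- random_sym(10, 11)
  noisy <- function(seed) {
    set.seed(seed)
    E <- matrix(0, 10, 10)
    E[upper.tri(E)] <- rnorm(45, 0, 0.05)
    M <- pmax(base + E + t(E), 0)
    colnames(M) <- rownames(M) <- colnames(base)
    as_assoc(M)
  }
  stable <- list(T1 = list(s1 = noisy(1), s2 = noisy(2), s3 = noisy(3)))
  rep_stable <- seasonal_stability_report(stable, n_perm = 500, seed = 2,
                                          two_sided = FALSE)
  expect_lt(min(rep_stable$combined$p[rep_stable$combined$territory == "T1" &
                                        rep_stable$combined$time_between == 1]),
            0.01)

  shuffled <- list(T1 = list(s1 = as_assoc(random_sym(10, 21)),
                             s2 = as_assoc(random_sym(10, 22)),
                             s3 = as_assoc(random_sym(10, 23))))
  rep_null <- seasonal_stability_report(shuffled, n_perm = 500, seed = 3,
                                        two_sided = FALSE)
  expect_gt(min(rep_null$combined$p), 0.001)
})
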