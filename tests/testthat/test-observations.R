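test_that("detection CSV round-trips with validation and row-indexed errors", {
  df <- data.frame(
    individual_id = c("A", "B", "A"),
    timestamp = c("2013-07-01 21:30:00", "2013-07-01 21:31:00",
                  "2013-07-02 03:10:00"),
    patch_id = "P1", territory_id = "T1", stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  det <- read_detections(path)
  expect_equal(nrow(det), 3)
  expect_s3_class(det$timestamp, "POSIXct")
  expect_equal(det$sex, rep("unknown", 3))

  write.csv(df[, setdiff(names(df), "patch_id")], path, row.names = FALSE)
  expect_error(read_detections(path), "patch_id")

  df_bad <- df
  df_bad$timestamp[2] <- "not-a-time"
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_detections(path), "row.*2")

  # duplicated identical rows are preserved (dedup is visit clustering's job)
  write.csv(rbind(df, df[1, ]), path, row.names = FALSE)
  expect_equal(nrow(read_detections(path)), 4)
})

test_that("noon-bounded sampling days follow the half-open convention", {
  t1 <- as.POSIXct("2013-07-01 13:00:00", tz = "UTC")
  t2 <- as.POSIXct("2013-07-02 11:59:00", tz = "UTC")
  t3 <- as.POSIXct("2013-07-02 12:00:00", tz = "UTC")
  expect_equal(assign_sampling_day(t1), assign_sampling_day(t2))
  expect_equal(assign_sampling_day(t3), assign_sampling_day(t1) + 1L)
  # boundary 0 gives calendar days
  expect_equal(assign_sampling_day(t1, 0), assign_sampling_day(t2, 0) - 1L)
  # partition: every timestamp maps to exactly one finite day index
  set.seed(1)
  ts <- as.POSIXct("2013-07-01", tz = "UTC") + runif(200, 0, 90 * 86400)
  d <- assign_sampling_day(ts)
  expect_true(all(is.finite(d)))
  expect_length(d, 200)
  # consecutive boundaries differ by exactly one day index
  eps <- as.POSIXct("2013-07-05 12:00:00", tz = "UTC")
  expect_equal(assign_sampling_day(eps - 1) + 1L, assign_sampling_day(eps))
})

test_that("visit clustering splits on gaps and pools interleaved individuals", {
  base <- as.POSIXct("2013-07-01 21:00:00", tz = "UTC")
  det <- data.frame(
    individual_id = c("A", "B", "A", "A"),
    timestamp = base + c(0, 2, 4, 20) * 60,
    patch_id = "P1", territory_id = "T1",
    sex = "unknown", status = "unknown", age_class = "unknown",
    stringsAsFactors = FALSE
  )
  v <- cluster_visits(det, gap_minutes = 10)
  expect_equal(length(unique(v$visit_id)), 2)
  first <- v[v$visit_id == min(v$visit_id), ]
  expect_setequal(first$individual_id, c("A", "B"))

  v1 <- cluster_visits(det[1, ], gap_minutes = 10)
  expect_equal(nrow(v1), 1)

  # invariant to input row order
  v_shuf <- cluster_visits(det[c(3, 1, 4, 2), ], gap_minutes = 10)
  expect_equal(v[order(v$visit_id, v$individual_id), ],
               v_shuf[order(v_shuf$visit_id, v_shuf$individual_id), ],
               ignore_attr = TRUE)
})

test_that("gambit of the group creates pairwise same-visit associations only", {
  base <- as.POSIXct("2013-07-01 21:00:00", tz = "UTC")
  det <- data.frame(
    individual_id = c("A", "B", "C", "A", "B"),
    # A,B,C share a visit; later A and B visit the same patch separately
    timestamp = base + c(0, 1, 2, 120, 200) * 60,
    patch_id = "P1", territory_id = "T1",
    sex = "unknown", status = "unknown", age_class = "unknown",
    stringsAsFactors = FALSE
  )
  g <- extract_groups(cluster_visits(det, gap_minutes = 10))
  counts <- tally_dyads(g)
  expect_equal(counts$x["A", "B"], 1) # via the shared visit only
  expect_equal(counts$x["A", "C"], 1)
  expect_equal(counts$x["B", "C"], 1)

  # same patch, same day, different visits: seen but not associated
  det2 <- det[4:5, ]
  g2 <- extract_groups(cluster_visits(det2, gap_minutes = 10))
  c2 <- tally_dyads(g2)
  expect_equal(c2$x["A", "B"], 0)
  expect_equal(c2$y_ab["A", "B"], 1)

  # a singleton visit yields no dyadic association
  g3 <- extract_groups(cluster_visits(det[1, , drop = FALSE]))
  expect_equal(sum(tally_dyads(g3)$x), 0)
})

test_that("minimum-day filter drops under-observed individuals and is idempotent", {
  groups <- make_groups(list(
    `1` = list(c("A", "B"), "C"),
    `2` = list(c("A", "C")),
    `3` = list(c("A", "B"), "C"),
    `4` = list(c("A", "C")),
    `5` = list("A", "C")
  ))
  # A seen 5 days, C seen 5 days, B seen 2 days
  f <- filter_min_days(groups, min_days = 5)
  expect_setequal(attr(f, "individuals"), c("A", "C"))
  expect_false("B" %in% f$individual_id)

  expect_equal(nrow(filter_min_days(groups, min_days = 1)), nrow(groups))

  f2 <- filter_min_days(f, min_days = 5)
  expect_equal(f2$individual_id, f$individual_id)

  # exclusion count equals a brute-force per-individual day tally
  g <- random_groups(n = 12, nd = 10, seed = 42)
  thr <- 4
  excluded_oracle <- sum(vapply(unique(g$individual_id), function(id) {
    length(unique(g$sampling_day[g$individual_id == id])) < thr
  }, TRUE))
  kept <- attr(filter_min_days(g, min_days = thr), "individuals")
  expect_equal(length(unique(g$individual_id)) - length(kept),
               excluded_oracle)
})

test_that("per-survey filter scope counts days within territory-season", {
  groups <- rbind(
    cbind(make_groups(list(`1` = list("A"), `2` = list("A"),
                           `3` = list(c("A", "B")))),
          season = "spring"),
    cbind(make_groups(list(`50` = list(c("A", "B")), `51` = list("B"),
                           `52` = list("B"))),
          season = "summer")
  )
  f <- filter_min_days(groups, min_days = 3, scope = "survey")
  # A qualifies in spring only, B in summer only
  expect_setequal(f$individual_id[f$season == "spring"], "A")
  expect_setequal(f$individual_id[f$season == "summer"], "B")
  expect_error(filter_min_days(make_groups(list(`1` = list("A"))),
                               min_days = 2, scope = "survey"),
               "season")
})

test_that("patch standardisation keeps the busiest patches per territory", {
  base <- as.POSIXct("2013-07-01 21:00:00", tz = "UTC")
  det <- data.frame(
    individual_id = "A",
    timestamp = base + seq_len(10) * 3600,
    patch_id = c(rep("P1", 5), rep("P2", 3), rep("P3", 2)),
    territory_id = "T1",
    sex = "unknown", status = "unknown", age_class = "unknown",
    stringsAsFactors = FALSE
  )
  out <- standardise_patches(det, 2)
  expect_setequal(unique(out$patch_id), c("P1", "P2"))
})
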