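test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_territories = 2, n_subordinates_per_sex = 2,
                    seasons = data.frame(label = "s1", start_day = 0,
                                         length_days = 15),
                    seed = 7)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$detections, b$detections)
  expect_identical(a$truth$dyad_propensity, b$truth$dyad_propensity)
  expect_identical(a$truth$events, b$truth$events)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_simulation(a, d1)
  p2 <- write_simulation(b, d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }

  s1 <- scenario("planted_communities", seed = 1)
  s2 <- scenario("planted_communities", seed = 1)
  expect_identical(s1$truth$community_of, s2$truth$community_of)
  expect_identical(s1$truth$dyad_propensity, s2$truth$dyad_propensity)
})

test_that("invalid configurations are rejected with the parameter named", {
  expect_error(sim_config(within_community_assoc = 1.4),
               "within_community_assoc")
  expect_error(sim_config(mortality_hazard = -0.1), "mortality_hazard")
  expect_error(sim_config(n_territories = 0), "n_territories")
  expect_error(sim_config(visit_rate = NaN), "visit_rate")
  expect_error(sim_config(within_community_assoc = 0.5, dyad_cv = 2), "cv")
  expect_error(scenario("not_a_preset"))
})

test_that("no individual is detected after its death day", {
  cfg <- sim_config(n_territories = 2, n_subordinates_per_sex = 3,
                    seasons = data.frame(label = "s1", start_day = 0,
                                         length_days = 60),
                    mortality_hazard = 0.02, dispersal_hazard = 0,
                    seed = 3)
  sim <- simulate_population(cfg)
  det <- sim$detections
  det$day <- assign_sampling_day(det$timestamp)
  day0 <- min(det$day)
  deaths <- sim$truth$events[sim$truth$events$event == "death", ]
  expect_gt(nrow(deaths), 0)
  for (r in seq_len(nrow(deaths))) {
    last_seen <- det$day[det$individual_id == deaths$individual_id[r]]
    if (length(last_seen) > 0) {
      expect_lt(max(last_seen) - day0, deaths$day[r])
    }
  }
})

test_that("dispersers relocate to a different territory", {
  cfg <- sim_config(n_territories = 3, n_subordinates_per_sex = 3,
                    seasons = data.frame(label = "s1", start_day = 0,
                                         length_days = 80),
                    mortality_hazard = 0, dispersal_hazard = 0.01,
                    visit_rate = 1, seed = 5)
  sim <- simulate_population(cfg)
  det <- sim$detections
  det$day <- assign_sampling_day(det$timestamp) - min(assign_sampling_day(det$timestamp))
  disp <- sim$truth$events[sim$truth$events$event == "dispersal", ]
  expect_gt(nrow(disp), 0)
  moved <- 0
  for (r in seq_len(nrow(disp))) {
    id <- disp$individual_id[r]
    home <- sim$truth$community_of[id]
    after <- det[det$individual_id == id & det$day >= disp$day[r], ]
    if (nrow(after) > 0) {
      moved <- moved + any(after$territory_id != home)
    }
  }
  expect_gt(moved, 0)
})

test_that("empirical co-detection frequency converges to the planted propensity", {
  # long horizon, diffuse patches so co-detection noise is negligible; the
  # latent value is a nightly co-visit rate, so the day-level association
  # probability is 1 - exp(-rate)
  cfg <- sim_config(n_territories = 1, patches_per_territory = 30,
                    n_subordinates_per_sex = 2,
                    seasons = data.frame(label = "s1", start_day = 0,
                                         length_days = 2000),
                    visit_rate = 0.3, within_community_assoc = 0.1,
                    between_community_assoc = 0, gregariousness_sd = 0,
                    dyad_cv = 0.5, dispersal_hazard = 0,
                    mortality_hazard = 0, seed = 11)
  sim <- simulate_population(cfg)
  g <- extract_groups(cluster_visits(sim$detections))
  counts <- tally_dyads(g, names(sim$truth$community_of))
  prop <- sim$truth$dyad_propensity
  ids <- counts$individuals
  checked <- 0
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      p_day <- 1 - exp(-prop[ids[a], ids[b]])
      freq <- counts$x[a, b] / 2000
      se <- sqrt(max(p_day * (1 - p_day), 1e-6) / 2000)
      expect_lt(abs(freq - p_day), 3 * se + 0.01)
      checked <- checked + 1
    }
  }
  expect_equal(checked, choose(length(ids), 2))
})

test_that("replacement recruitment keeps the population size constant", {
  cfg <- sim_config(n_territories = 1, n_subordinates_per_sex = 4,
                    seasons = data.frame(label = "s1", start_day = 0,
                                         length_days = 100),
                    mortality_hazard = 0.01, dispersal_hazard = 0,
                    recruitment = "replacement", visit_rate = 2,
                    seed = 13)
  sim <- simulate_population(cfg)
  det <- sim$detections
  det$day <- assign_sampling_day(det$timestamp)
  n_per_day <- tapply(det$individual_id, det$day,
                      function(x) length(unique(x)))
  # detected count stays near the 10 occupied positions throughout
  expect_gt(mean(head(n_per_day, 20)), 7)
  expect_gt(mean(tail(n_per_day, 20)), 7)
  # recruits appear with fresh ids after deaths
  expect_gt(length(unique(det$individual_id)), 10)
  expect_error(sim_config(recruitment = "replacement",
                          dispersal_hazard = 0.01), "recruitment")
})

test_that("gregariousness multipliers average one and spread with the sd", {
  cfg <- sim_config(n_territories = 4, n_subordinates_per_sex = 5,
                    gregariousness_sd = 0.5, seed = 2)
  sim <- simulate_population(cfg)
  g <- sim$truth$gregariousness
  expect_gt(mean(g), 0.8)
  expect_lt(mean(g), 1.2)
  expect_gt(sd(log(g)), 0.3)
})
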