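# Configuration-driven orchestration of the full analysis.

#' Build a validated pipeline configuration
#'
#' @param detections path to a detection CSV, or an in-memory detection
#'   table; exactly one of `detections` / `preset` / `sim` must be given.
#' @param preset a [scenario()] preset name to simulate input data.
#' @param sim a [sim_config()] for custom simulated input.
#' @param boundary_hour sampling-period boundary hour (default 12).
#' @param gap_minutes visit-clustering gap (default 10).
#' @param min_days minimum observation days filter (default 5).
#' @param filter_scope `"survey"` for the seasonal networks (the pooled
#'   network always uses a pooled-scope filter).
#' @param season_windows data.frame (`label`, `start_day`, `length_days`)
#'   assigning sampling days to seasons; inferred from the simulation config
#'   when simulating, required for real data if seasonal analyses are on.
#' @param n_perm,trials permutation-test effort.
#' @param mantel_perm permutations for seasonal stability tests.
#' @param run_permutations,run_differentiation,run_communities,run_temporal,
#'   run_stability stage toggles.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it and records it in the output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(detections = NULL, preset = NULL, sim = NULL,
                            boundary_hour = 12, gap_minutes = 10,
                            min_days = 5, filter_scope = "survey",
                            season_windows = NULL,
                            n_perm = 1000, trials = 500, mantel_perm = 1000,
                            run_permutations = TRUE,
                            run_differentiation = TRUE,
                            run_communities = TRUE,
                            run_temporal = TRUE,
                            run_stability = TRUE,
                            seed = 1L) {
  n_sources <- sum(!is.null(detections), !is.null(preset), !is.null(sim))
  if (n_sources != 1) {
    stop_named("detections/preset/sim", "exactly one input source required")
  }
  check_nonneg(boundary_hour, "boundary_hour")
  if (boundary_hour >= 24) stop_named("boundary_hour", "must be in [0, 24)")
  if (gap_minutes <= 0) stop_named("gap_minutes", "must be > 0")
  check_count(min_days, "min_days")
  check_count(n_perm, "n_perm")
  check_count(trials, "trials")
  check_count(mantel_perm, "mantel_perm")
  check_count(seed, "seed", min = 0)
  structure(list(detections = detections, preset = preset, sim = sim,
                 boundary_hour = boundary_hour, gap_minutes = gap_minutes,
                 min_days = min_days, filter_scope = filter_scope,
                 season_windows = season_windows,
                 n_perm = n_perm, trials = trials,
                 mantel_perm = mantel_perm,
                 run_permutations = run_permutations,
                 run_differentiation = run_differentiation,
                 run_communities = run_communities,
                 run_temporal = run_temporal,
                 run_stability = run_stability,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# season label per sampling day (absolute index relative to day0)
season_of_day <- function(day, windows, day0) {
  rel <- day - day0
  out <- rep(NA_character_, length(day))
  for (i in seq_len(nrow(windows))) {
    sel <- rel >= windows$start_day[i] &
      rel < windows$start_day[i] + windows$length_days[i]
    out[sel] <- windows$label[i]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) detections, builds visits, groups and seasonal
#' networks, and runs every enabled stage: per territory x season network -
#' association matrix, differentiation estimate, permutation tests,
#' community detection; pooled - association matrix, LAR/NAR/LIR with decay
#' model fits; per territory - seasonal stability tests. Stage failures on
#' individual networks are caught and reported with the stage name, and
#' partial outputs preserved.
#'
#' @param config a [pipeline_config()].
#' @return A `report_bundle`: list with `networks` (per territory x season:
#'   matrix, estimates, tests, partition), `pooled`, `stability`, `groups`,
#'   and a `manifest` recording seeds and settings.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  windows <- config$season_windows
  if (!is.null(config$preset)) {
    simd <- scenario(config$preset, seed = config$seed)
    det <- simd$detections
    truth <- simd$truth
    windows <- windows %||% data.frame(label = "s1", start_day = 0,
                                       length_days = 10000)
  } else if (!is.null(config$sim)) {
    simd <- simulate_population(config$sim)
    det <- simd$detections
    truth <- simd$truth
    windows <- windows %||% config$sim$seasons
  } else if (is.character(config$detections)) {
    det <- read_detections(config$detections)
  } else {
    det <- validate_detections(config$detections)
  }

  visits <- cluster_visits(det, config$gap_minutes, config$boundary_hour)
  groups <- extract_groups(visits)
  day0 <- min(groups$sampling_day)
  if (!is.null(windows)) {
    groups$season <- season_of_day(groups$sampling_day, windows, day0)
    groups <- groups[!is.na(groups$season), , drop = FALSE]
  } else {
    groups$season <- "all"
  }

  failures <- list()
  note_failure <- function(stage, id, e) {
    failures[[length(failures) + 1]] <<- data.frame(
      stage = stage, network = id, message = conditionMessage(e),
      stringsAsFactors = FALSE)
    NULL
  }

  # seasonal networks: survey-scope filter
  g_seasonal <- filter_min_days(groups, config$min_days, scope = "survey")
  nets <- list()
  combos <- unique(g_seasonal[c("territory_id", "season")])
  combos <- combos[order(combos$territory_id, combos$season), , drop = FALSE]
  seed_k <- config$seed
  for (r in seq_len(nrow(combos))) {
    terr <- combos$territory_id[r]
    seas <- combos$season[r]
    id <- paste(terr, seas, sep = ":")
    g <- g_seasonal[g_seasonal$territory_id == terr &
                      g_seasonal$season == seas, , drop = FALSE]
    if (length(unique(g$individual_id)) < 2) next
    counts <- tally_dyads(g)
    m <- simple_ratio(counts)
    net <- list(id = id, territory = terr, season = seas,
                n_individuals = length(m$individuals),
                n_days = counts$n_days, counts = counts, matrix = m)
    if (config$run_differentiation) {
      net$differentiation <- tryCatch(fit_differentiation(counts),
                                      error = function(e)
                                        note_failure("differentiation", id, e),
                                      warning = function(w) NULL)
    }
    if (config$run_permutations) {
      seed_k <- seed_k + 1L
      net$perm_groups <- tryCatch(
        permute_groups_within_days(g, config$n_perm, config$trials, seed_k),
        error = function(e) note_failure("permute_groups", id, e))
      seed_k <- seed_k + 1L
      net$perm_assoc <- tryCatch(
        permute_associations_within_days(g, config$n_perm, config$trials,
                                         seed_k),
        error = function(e) note_failure("permute_associations", id, e))
    }
    if (config$run_communities) {
      net$communities <- tryCatch(detect_communities(m),
                                  error = function(e)
                                    note_failure("communities", id, e))
    }
    nets[[id]] <- net
  }

  # pooled network: pooled-scope filter
  g_pooled <- filter_min_days(groups, config$min_days, scope = "pooled")
  pooled <- NULL
  if (length(unique(g_pooled$individual_id)) >= 2) {
    counts <- tally_dyads(g_pooled)
    m <- simple_ratio(counts)
    pooled <- list(counts = counts, matrix = m,
                   n_individuals = length(m$individuals))
    if (config$run_communities) {
      pooled$communities <- tryCatch(detect_communities(m),
                                     error = function(e)
                                       note_failure("communities", "pooled", e))
    }
    if (config$run_temporal) {
      pooled$lar <- tryCatch(lagged_association_rate(g_pooled),
                             error = function(e)
                               note_failure("lar", "pooled", e))
      pooled$nar <- tryCatch(null_association_rate(g_pooled),
                             error = function(e)
                               note_failure("nar", "pooled", e))
      pooled$lir <- tryCatch(
        lagged_identification_rate(unique(det[c("individual_id",
                                                "timestamp")]),
                                   boundary_hour = config$boundary_hour),
        error = function(e) note_failure("lir", "pooled", e))
      if (!is.null(pooled$lar)) {
        pooled$lar_models <- tryCatch(
          fit_decay_models(pooled$lar, seed = config$seed),
          error = function(e) note_failure("lar_models", "pooled", e))
      }
      if (!is.null(pooled$lir)) {
        pooled$lir_models <- tryCatch(
          fit_decay_models(pooled$lir, seed = config$seed),
          error = function(e) note_failure("lir_models", "pooled", e))
      }
    }
  }

  stability <- NULL
  if (config$run_stability && length(nets) > 0) {
    by_terr <- split(nets, vapply(nets, `[[`, "", "territory"))
    networks <- lapply(by_terr, function(ns) {
      ms <- lapply(ns, `[[`, "matrix")
      names(ms) <- vapply(ns, `[[`, "", "season")
      # chronological season order from the windows table
      if (!is.null(windows)) {
        ms <- ms[intersect(windows$label, names(ms))]
      }
      ms
    })
    stability <- tryCatch(
      seasonal_stability_report(networks, n_perm = config$mantel_perm,
                                seed = config$seed),
      error = function(e) note_failure("stability", "all", e))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("foxsna")),
    seed = config$seed,
    settings = config[c("boundary_hour", "gap_minutes", "min_days",
                        "n_perm", "trials", "mantel_perm")],
    n_networks = length(nets),
    n_detections = nrow(det),
    timestamp = NA_character_ # deterministic output: no wall-clock stamp
  )
  structure(list(networks = nets, pooled = pooled, stability = stability,
                 groups = groups, truth = truth,
                 failures = if (length(failures) > 0)
                   do.call(rbind, failures) else NULL,
                 manifest = manifest),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("Report bundle: %d territory-season networks, %d detections\n",
              x$manifest$n_networks, x$manifest$n_detections))
  if (!is.null(x$pooled)) {
    cat(sprintf("  pooled network: %d individuals\n",
                x$pooled$n_individuals))
  }
  if (!is.null(x$failures)) {
    cat(sprintf("  %d stage failure(s)\n", nrow(x$failures)))
  }
  invisible(x)
}

#' Write the flat CSV outputs of a report bundle
#'
#' Every number in the report is written as diffable flat CSV: association
#' edge lists, differentiation estimates, permutation tables, partitions,
#' lag curves and model tables, and the stability table.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  diff_rows <- perm_rows <- part_rows <- list()
  for (net in bundle$networks) {
    if (!is.null(net$differentiation)) {
      e <- net$differentiation
      diff_rows[[net$id]] <- data.frame(network_id = net$id, S = e$S,
                                        r = e$r, mu = e$mu, band = e$band,
                                        stringsAsFactors = FALSE)
    }
    if (!is.null(net$perm_groups)) {
      perm_rows[[paste0(net$id, "_g")]] <-
        permutation_table(net$perm_groups, net$id)
    }
    if (!is.null(net$perm_assoc)) {
      perm_rows[[paste0(net$id, "_a")]] <-
        permutation_table(net$perm_assoc, net$id)
    }
    if (!is.null(net$communities)) {
      p <- net$communities$selected
      part_rows[[net$id]] <- data.frame(
        network_id = net$id, individual_id = names(p$labels),
        community = unname(p$labels), method = p$method, Q = p$Q,
        stringsAsFactors = FALSE)
    }
  }
  add(do.call(rbind, diff_rows), "differentiation.csv")
  add(do.call(rbind, perm_rows), "permutation_tests.csv")
  add(do.call(rbind, part_rows), "partitions.csv")
  if (!is.null(bundle$pooled)) {
    if (!is.null(bundle$pooled$lar)) {
      add(as.data.frame(bundle$pooled$lar), "lar_pooled.csv")
    }
    if (!is.null(bundle$pooled$lir)) {
      add(as.data.frame(bundle$pooled$lir), "lir_pooled.csv")
    }
    if (!is.null(bundle$pooled$lar_models)) {
      add(decay_table(bundle$pooled$lar_models), "lar_models.csv")
    }
    if (!is.null(bundle$pooled$lir_models)) {
      add(decay_table(bundle$pooled$lir_models), "lir_models.csv")
    }
  }
  if (!is.null(bundle$stability)) {
    add(bundle$stability$pairs, "stability_pairs.csv")
    add(bundle$stability$combined, "stability_combined.csv")
  }
  add(bundle$failures, "failures.csv")
  invisible(paths)
}
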