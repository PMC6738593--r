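#' Read a detection table from CSV
#'
#' A detection record is one timestamped identification of one individual at
#' one food patch. The CSV must contain the columns `individual_id`,
#' `timestamp`, `patch_id` and `territory_id`; `sex`, `status` and `age_class`
#' are optional and default to `"unknown"`. Timestamps must be ISO-8601
#' (`YYYY-MM-DD HH:MM[:SS]`); they are parsed in UTC.
#'
#' Duplicated rows are preserved: collapsing repeat triggers of the same
#' camera is the job of [cluster_visits()], not ingestion.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with columns `individual_id`, `timestamp`
#'   (`POSIXct`), `patch_id`, `territory_id`, `sex`, `status`, `age_class`.
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_detections(df)
}

#' Validate (and normalise) an in-memory detection table
#'
#' @param df a data.frame with the columns described in [read_detections()].
#' @return the validated table with parsed timestamps and explicit
#'   `"unknown"` attribute levels.
#' @export
validate_detections <- function(df) {
  required <- c("individual_id", "timestamp", "patch_id", "territory_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_named(missing[1], "required column missing from detection table")
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    raw <- as.character(df$timestamp)
    ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01",
                     tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")) {
      need <- is.na(ts)
      if (!any(need)) break
      ts[need] <- as.POSIXct(strptime(raw[need], fmt, tz = "UTC"))
    }
    bad <- which(is.na(ts) & !is.na(raw))
    if (length(bad) > 0) {
      stop_named("timestamp", sprintf(
        "unparseable timestamp in row(s) %s",
        paste(head(bad, 5), collapse = ", ")
      ))
    }
    df$timestamp <- ts
  }
  for (col in c("individual_id", "patch_id", "territory_id")) {
    df[[col]] <- as.character(df[[col]])
    if (any(is.na(df[[col]]) | df[[col]] == "")) {
      stop_named(col, "ids must be non-empty")
    }
  }
  for (col in c("sex", "status", "age_class")) {
    if (is.null(df[[col]])) df[[col]] <- "unknown"
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]]) | df[[col]] == ""] <- "unknown"
  }
  df[c("individual_id", "timestamp", "patch_id", "territory_id",
       "sex", "status", "age_class")]
}

#' Assign a sampling-day index to timestamps
#'
#' Sampling periods are days that start and end at a fixed boundary hour
#' (noon by default), a natural break in the nocturnal activity of the study
#' animals, so that one night of activity falls inside one sampling period.
#' The interval is half-open: timestamps in `[boundary day d, boundary day
#' d+1)` map to day index `d`, counted from the Unix epoch.
#'
#' @param t a `POSIXct` vector (UTC).
#' @param boundary_hour hour of day at which sampling periods begin
#'   (default 12; 0 gives calendar days).
#' @return integer vector of sampling-day indices.
#' @export
assign_sampling_day <- function(t, boundary_hour = 12) {
  if (!inherits(t, "POSIXct")) stop_named("t", "must be POSIXct")
  check_nonneg(boundary_hour, "boundary_hour")
  if (boundary_hour >= 24) stop_named("boundary_hour", "must be in [0, 24)")
  as.integer(floor((as.numeric(t) / 3600 - boundary_hour) / 24))
}

#' Cluster detections into patch visits
#'
#' Within each patch, detections sorted by time are split into visits wherever
#' the gap between consecutive detections exceeds `gap_minutes`. All
#' individuals detected within one visit are its members; this is the pooling
#' step that later yields grouped observations. The default 10-minute gap is a
#' documented stand-in: the appropriate value depends on camera trigger
#' behaviour and should be set from knowledge of the survey hardware.
#'
#' @param detections a validated detection table ([read_detections()]).
#' @param gap_minutes positive gap (minutes) separating visits.
#' @param boundary_hour passed to [assign_sampling_day()].
#' @return A visit table: one row per (visit, member) with columns `visit_id`,
#'   `sampling_day`, `patch_id`, `territory_id`, `individual_id`. The
#'   sampling day of a visit is that of its first detection.
#' @export
cluster_visits <- function(detections, gap_minutes = 10, boundary_hour = 12) {
  if (!is.numeric(gap_minutes) || gap_minutes <= 0) {
    stop_named("gap_minutes", "must be > 0")
  }
  det <- detections[order(detections$patch_id, detections$timestamp,
                          detections$individual_id), , drop = FALSE]
  n <- nrow(det)
  if (n == 0) {
    return(data.frame(visit_id = integer(0), sampling_day = integer(0),
                      patch_id = character(0), territory_id = character(0),
                      individual_id = character(0),
                      stringsAsFactors = FALSE))
  }
  new_patch <- c(TRUE, det$patch_id[-1] != det$patch_id[-n])
  gap <- c(Inf, diff(as.numeric(det$timestamp)) / 60)
  new_visit <- new_patch | gap > gap_minutes
  det$visit_id <- cumsum(new_visit)
  first <- !duplicated(det$visit_id)
  day_of_visit <- assign_sampling_day(det$timestamp[first], boundary_hour)
  det$sampling_day <- day_of_visit[det$visit_id]
  out <- unique(det[c("visit_id", "sampling_day", "patch_id", "territory_id",
                      "individual_id")])
  rownames(out) <- NULL
  out
}

#' Extract grouped observations from a visit table
#'
#' Applies the gambit of the group: every pair of individuals sharing a patch
#' visit is taken to be associating. One group observation is emitted per
#' visit (singleton visits included: animals observed alone are legitimate
#' observations and define isolates). Two individuals in the same patch on the
#' same day but in *different* visits are not associated here; that looser
#' relation is the same-day patch-use network of [patch_use_network()].
#'
#' @param visits a visit table from [cluster_visits()].
#' @return A group table: one row per (group, member) with columns `group_id`,
#'   `sampling_day`, `patch_id`, `territory_id`, `individual_id`.
#' @export
extract_groups <- function(visits) {
  out <- visits
  names(out)[names(out) == "visit_id"] <- "group_id"
  out <- out[order(out$group_id, out$individual_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop individuals observed on too few sampling days
#'
#' Individuals identified on fewer than `min_days` distinct sampling days are
#' removed from group memberships (and groups emptied of all members vanish).
#' The threshold reduces bias from poorly sampled animals. The scope controls
#' the unit within which days are counted: `"pooled"` counts days across the
#' whole table; `"survey"` counts within each territory x season survey and
#' requires a `season` column on the groups.
#'
#' @param groups a group table ([extract_groups()]), optionally with a
#'   `season` column when `scope = "survey"`.
#' @param min_days minimum number of distinct sampling days (default 5).
#' @param scope `"pooled"` or `"survey"`.
#' @return the filtered group table; kept individuals in
#'   `attr(, "individuals")`.
#' @export
filter_min_days <- function(groups, min_days = 5,
                            scope = c("pooled", "survey")) {
  scope <- match.arg(scope)
  check_count(min_days, "min_days", min = 1)
  if (scope == "pooled") {
    seen <- unique(groups[c("individual_id", "sampling_day")])
    days <- table(seen$individual_id)
    keep_id <- names(days)[days >= min_days]
    kept <- groups[groups$individual_id %in% keep_id, , drop = FALSE]
  } else {
    if (is.null(groups$season)) {
      stop_named("season", "scope = \"survey\" needs a season column")
    }
    key <- paste(groups$territory_id, groups$season, groups$individual_id)
    seen <- unique(data.frame(key = key, day = groups$sampling_day))
    days <- table(seen$key)
    kept <- groups[days[key] >= min_days, , drop = FALSE]
    keep_id <- unique(kept$individual_id)
  }
  rownames(kept) <- NULL
  attr(kept, "individuals") <- sort(unique(kept$individual_id))
  kept
}

#' Standardise the number of patches per territory
#'
#' Network data collected with unequal sampling effort are not directly
#' comparable, so surveys can be standardised to the same number of patches
#' per territory by keeping the `n_patches` most visited patches (ties broken
#' by patch id) and dropping detections at the rest.
#'
#' @param detections a validated detection table.
#' @param n_patches patches to keep per territory.
#' @return the restricted detection table.
#' @export
standardise_patches <- function(detections, n_patches) {
  check_count(n_patches, "n_patches", min = 1)
  keep <- unlist(lapply(split(detections, detections$territory_id), function(d) {
    counts <- sort(table(d$patch_id), decreasing = TRUE)
    names(counts)[seq_len(min(n_patches, length(counts)))]
  }))
  out <- detections[detections$patch_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
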