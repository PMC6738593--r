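#' Tally dyadic association counts over sampling periods
#'
#' For every unordered dyad (A, B) and sampling day, exactly one of five
#' things happens: both were associated (`x`), both were identified but not
#' associated (`y_ab`), only A was identified (`y_a`), only B (`y_b`), or
#' neither. Association is binarised at the day level - several co-visits on
#' one day count once, because the simple ratio index is defined over
#' sampling periods, not visits.
#'
#' @param groups a group table ([extract_groups()]).
#' @param individuals optional character vector fixing the individual set and
#'   ordering; defaults to everyone appearing in `groups`.
#' @return An object of class `dyad_counts`: a list with `individuals`,
#'   matrices `x`, `y_ab`, `y_a`, `y_b`, `d` (all symmetric, zero diagonal;
#'   `y_a[i, j]` counts days only the row individual `i` was identified), and
#'   `n_days`, the number of distinct sampling days.
#' @export
tally_dyads <- function(groups, individuals = NULL) {
  individuals <- individuals %||% sort(unique(groups$individual_id))
  n <- length(individuals)
  days <- sort(unique(groups$sampling_day))
  nd <- length(days)
  ind_idx <- match(groups$individual_id, individuals)
  day_idx <- match(groups$sampling_day, days)
  keep <- !is.na(ind_idx)

  # seen[d, i]: individual i identified on day d
  seen <- matrix(FALSE, nd, n)
  seen[cbind(day_idx[keep], ind_idx[keep])] <- TRUE

  # day-level association: both members of a dyad in >= 1 common group
  x <- matrix(0, n, n)
  gkey <- groups$group_id[keep]
  gi <- ind_idx[keep]
  gd <- day_idx[keep]
  for (d in seq_len(nd)) {
    sel <- gd == d
    if (!any(sel)) next
    co <- matrix(0, n, n)
    for (members in split(gi[sel], gkey[sel])) {
      members <- unique(members)
      if (length(members) >= 2) co[members, members] <- 1
    }
    diag(co) <- 0
    x <- x + (co > 0)
  }

  seen_num <- seen + 0
  n_both <- crossprod(seen_num)       # days both identified
  n_i <- colSums(seen_num)            # days each identified
  y_ab <- n_both - x
  y_a <- matrix(n_i, n, n) - n_both   # row individual only
  y_b <- t(y_a)
  d <- x + y_ab + y_a + y_b           # = n_i + n_j - n_both
  diag(x) <- diag(y_ab) <- diag(y_a) <- diag(y_b) <- diag(d) <- 0
  dimnames(x) <- dimnames(y_ab) <- dimnames(y_a) <- dimnames(y_b) <-
    dimnames(d) <- list(individuals, individuals)
  structure(list(individuals = individuals, x = x, y_ab = y_ab,
                 y_a = y_a, y_b = y_b, d = d, n_days = nd),
            class = "dyad_counts")
}

#' Simple ratio index matrix from dyadic counts
#'
#' `SRI = x / (x + y_ab + y_a + y_b)`: the fraction of sampling periods on
#' which a dyad was associated, out of those in which at least one member was
#' identified. Dyads whose denominator is zero (never identified on a common
#' time base) are *masked*, not treated as zero associations: the `mask`
#' matrix marks them and downstream summary statistics exclude them by
#' default.
#'
#' @param counts a `dyad_counts` object.
#' @return An object of class `association_matrix`: list with `individuals`,
#'   `sri` (symmetric, in \[0,1\], masked entries 0), `d` (denominators) and
#'   logical `mask` (TRUE where the index is undefined).
#' @export
simple_ratio <- function(counts) {
  stopifnot(inherits(counts, "dyad_counts"))
  d <- counts$d
  sri <- ifelse(d > 0, counts$x / ifelse(d > 0, d, 1), 0)
  mask <- d == 0
  diag(mask) <- TRUE
  diag(sri) <- 0
  structure(list(individuals = counts$individuals, sri = sri, d = d,
                 mask = mask),
            class = "association_matrix")
}

#' Per-individual association summaries
#'
#' For each individual: mean SRI (the proportion of time spent associating,
#' averaged over its unmasked dyads), maximum SRI (time spent with the
#' closest companion), mean daily gregariousness (distinct associates per day
#' on which the individual was identified) and an isolate flag (never
#' observed in a group of two or more).
#'
#' @param m an `association_matrix`.
#' @param groups the group table the matrix was built from.
#' @return data.frame with one row per individual.
#' @export
individual_summaries <- function(m, groups) {
  stopifnot(inherits(m, "association_matrix"))
  ids <- m$individuals
  n <- length(ids)
  mean_sri <- max_sri <- numeric(n)
  for (i in seq_len(n)) {
    ok <- !m$mask[i, ]
    ok[i] <- FALSE
    mean_sri[i] <- if (any(ok)) mean(m$sri[i, ok]) else 0
    max_sri[i] <- if (any(ok)) max(m$sri[i, ok]) else 0
  }
  greg <- daily_gregariousness(groups)
  data.frame(
    individual_id = ids,
    mean_sri = mean_sri,
    max_sri = max_sri,
    mean_daily_associates = unname(greg$mean_daily[match(ids, greg$individual_id)]),
    isolate = unname(greg$isolate[match(ids, greg$individual_id)]),
    stringsAsFactors = FALSE
  )
}

# mean number of distinct associates per day seen, and isolate flag
daily_gregariousness <- function(groups) {
  ids <- sort(unique(groups$individual_id))
  assoc_by_day <- new.env()
  seen_days <- new.env()
  for (id in ids) {
    assign(id, list(), envir = assoc_by_day)
    assign(id, character(0), envir = seen_days)
  }
  key <- paste(groups$group_id)
  for (g in split(groups, key)) {
    members <- unique(g$individual_id)
    day <- as.character(g$sampling_day[1])
    for (mbr in members) {
      sd <- get(mbr, envir = seen_days)
      if (!(day %in% sd)) assign(mbr, c(sd, day), envir = seen_days)
      if (length(members) >= 2) {
        lst <- get(mbr, envir = assoc_by_day)
        lst[[day]] <- unique(c(lst[[day]], setdiff(members, mbr)))
        assign(mbr, lst, envir = assoc_by_day)
      }
    }
  }
  mean_daily <- vapply(ids, function(id) {
    days <- get(id, envir = seen_days)
    if (length(days) == 0) return(0)
    lst <- get(id, envir = assoc_by_day)
    counts <- vapply(days, function(d) length(lst[[d]] %||% character(0)), 0)
    mean(counts)
  }, 0)
  isolate <- vapply(ids, function(id) {
    length(get(id, envir = assoc_by_day)) == 0
  }, TRUE)
  data.frame(individual_id = ids, mean_daily = mean_daily, isolate = isolate,
             stringsAsFactors = FALSE)
}

#' Identify isolates
#'
#' @param groups a group table.
#' @return character vector of individuals never observed in a group of
#'   two or more.
#' @export
isolates <- function(groups) {
  g <- daily_gregariousness(groups)
  g$individual_id[g$isolate]
}

#' Export an association matrix
#'
#' @param m an `association_matrix`.
#' @param path output path.
#' @param format `"matrix"` (square CSV with id header row/column),
#'   `"edgelist"` (long CSV `i,j,sri,d` over unmasked dyads) or `"graphml"`
#'   (via igraph, `sri` as edge weight) for external layout tools.
#' @return `path`, invisibly.
#' @export
write_association <- function(m, path,
                              format = c("matrix", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "matrix") {
    out <- as.data.frame(m$sri)
    write.csv(cbind(individual_id = m$individuals, out), path,
              row.names = FALSE)
  } else if (format == "edgelist") {
    p <- dyad_pairs(length(m$individuals))
    keep <- !m$mask[p]
    df <- data.frame(i = m$individuals[p[keep, 1]],
                     j = m$individuals[p[keep, 2]],
                     sri = m$sri[p[keep, , drop = FALSE]],
                     d = m$d[p[keep, , drop = FALSE]])
    write.csv(df, path, row.names = FALSE)
  } else {
    g <- association_igraph(m)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

# weighted igraph over unmasked positive edges
association_igraph <- function(m, labels = NULL) {
  w <- m$sri
  w[m$mask] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(labels)) {
    igraph::V(g)$community <- as.character(labels[m$individuals])
  }
  g
}
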