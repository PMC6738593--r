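# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

stop_named <- function(param, msg) {
  stop(sprintf("[%s] %s", param, msg), call. = FALSE)
}

# Beta(alpha, beta) parameterised by mean m in (0,1) and coefficient of
# variation cv >= 0. Requires cv^2 < (1 - m)/m, otherwise no Beta exists.
beta_from_mean_cv <- function(m, cv) {
  if (m <= 0 || m >= 1) stop_named("mean", "Beta mean must be in (0,1)")
  if (cv < 0) stop_named("cv", "coefficient of variation must be >= 0")
  if (cv^2 >= (1 - m) / m) {
    stop_named("cv", sprintf(
      "cv too large for Beta with mean %.3f (needs cv < %.3f)",
      m, sqrt((1 - m) / m)
    ))
  }
  s <- (1 - m) / (m * cv^2) - 1 # alpha + beta
  list(alpha = m * s, beta = (1 - m) * s)
}

# draw dyadic probabilities with a given mean and CV; cv = 0 degenerates to
# the constant mean
draw_beta_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  par <- beta_from_mean_cv(m, cv)
  rbeta(n, par$alpha, par$beta)
}

# unordered dyad indices over n individuals, in upper.tri()'s column-major
# order so vectors over dyads align with sym_from_upper()
dyad_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

upper_vec <- function(m) m[upper.tri(m)]

sym_from_upper <- function(v, n, diag = 0) {
  m <- matrix(diag, n, n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop_named(name, "must be a single finite probability in [0,1]")
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x))
    stop_named(name, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    stop_named(name, "must be a single finite non-negative number")
  x
}
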