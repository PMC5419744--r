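# Penalized least-squares change-point engine.
#
# Minimises  sum(segment RSS) + penalty * (number of segments)  over all
# segmentations with segments of at least `min_len` points (equivalently
# RSS + penalty * breakpoints, up to a constant). Dynamic programming from
# the right; reconstruction from the left picks the earliest boundary among
# cost ties, so the solution is the lexicographically smallest optimal
# change-point vector ("earliest change point wins").

# Vectorised segment cost for piecewise-constant fits: cost(i, j) for fixed i
# and all j in js. Returns RSS around the segment mean.
cost_const_factory <- function(y) {
  s1 <- cumsum(c(0, y)); s2 <- cumsum(c(0, y^2))
  function(i, js) {
    n <- js - i + 1
    sy <- s1[js + 1] - s1[i]
    syy <- s2[js + 1] - s2[i]
    pmax(0, syy - sy^2 / n)
  }
}

# Piecewise-linear segment cost: OLS line RSS on (x, y) over i..j.
cost_linear_factory <- function(x, y) {
  sx <- cumsum(c(0, x)); sxx <- cumsum(c(0, x^2))
  sy <- cumsum(c(0, y)); syy <- cumsum(c(0, y^2))
  sxy <- cumsum(c(0, x * y))
  function(i, js) {
    n <- js - i + 1
    Sx <- sx[js + 1] - sx[i]; Sxx <- sxx[js + 1] - sxx[i]
    Sy <- sy[js + 1] - sy[i]; Syy <- syy[js + 1] - syy[i]
    Sxy <- sxy[js + 1] - sxy[i]
    cxx <- Sxx - Sx^2 / n
    cyy <- Syy - Sy^2 / n
    cxy <- Sxy - Sx * Sy / n
    out <- cyy - ifelse(cxx > 0, cxy^2 / cxx, 0)
    pmax(0, out)
  }
}

# Core DP. cost(i, js) must be vectorised over js. Returns integer vector of
# segment start indices (first element is always 1).
cp_segment <- function(n, cost, penalty, min_len = 1L) {
  min_len <- max(1L, as.integer(min_len))
  if (n < min_len) abort("series shorter than the minimum segment length")
  G <- c(numeric(n), 0)          # G[i] = optimal cost of points i..n; G[n+1] = 0
  nxt <- integer(n)              # chosen segment end for segment starting at i
  for (i in n:1) {
    if (i + min_len - 1L > n) { G[i] <- Inf; nxt[i] <- n; next }
    js <- seq.int(i + min_len - 1L, n)
    # a trailing fragment shorter than min_len is not allowed
    ok <- (js == n) | (n - js >= min_len)
    js <- js[ok]
    if (!length(js)) { G[i] <- Inf; nxt[i] <- n; next }
    vals <- cost(i, js) + penalty + G[js + 1L]
    k <- which.min(vals)         # earliest boundary on ties
    G[i] <- vals[k]; nxt[i] <- js[k]
  }
  starts <- integer(0)
  i <- 1L
  while (i <= n) { starts <- c(starts, i); i <- nxt[i] + 1L }
  starts
}

# Exhaustive reference optimiser over all breakpoint placements (small n),
# same cost and tie rule: lexicographically smallest optimal placement.
# Exported for use as an independent check; not part of the analysis path.
#' Brute-force penalized change-point reference
#'
#' Enumerates every admissible set of change points (up to `max_breaks`) and
#' returns the minimiser of `RSS + penalty * segments`, taking the
#' lexicographically smallest placement on exact cost ties. Intended as an
#' independent reference for validating the dynamic-programming detector on
#' short traces.
#'
#' @param y Numeric series (piecewise-constant model).
#' @param penalty Penalty per segment.
#' @param max_breaks Cap on the change-point count to enumerate; the search
#'   stops earlier once `best cost < penalty * (k + 2)`, at which point any
#'   solution with more than `k` breaks costs at least `penalty * (k + 2)`
#'   even with zero residual, so the enumeration is provably exhaustive.
#' @param min_len Minimum segment length in points.
#' @return List with `starts` (segment start indices) and `cost`.
#' @export
brute_force_steps <- function(y, penalty, max_breaks = 8L, min_len = 1L) {
  n <- length(y)
  s1 <- cumsum(c(0, y)); s2 <- cumsum(c(0, y^2))
  seg_cost_vec <- function(is, js) {   # elementwise RSS of segments is..js
    m <- js - is + 1
    sy <- s1[js + 1] - s1[is]
    pmax(0, s2[js + 1] - s2[is] - sy^2 / m)
  }
  # tie order: lexicographic on breakpoint vectors padded with +Inf (an
  # earlier additional breakpoint beats stopping), matching the DP's
  # earliest-boundary-first reconstruction
  lex_less <- function(a, b) {
    k <- max(length(a), length(b))
    a <- c(a, rep(Inf, k - length(a)))
    b <- c(b, rep(Inf, k - length(b)))
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  best <- list(starts = 1L, cost = seg_cost_vec(1L, n) + penalty,
               breaks = numeric(0))
  for (k in seq_len(min(max_breaks, n - 1L))) {
    if (best$cost < penalty * (k + 1)) break  # more breaks cannot win
    combos <- utils::combn(n - 1L, k)         # breakpoints after index b
    starts <- rbind(1L, combos + 1L)
    ends <- rbind(combos, n)
    costs <- numeric(ncol(combos))
    ok <- rep(TRUE, ncol(combos))
    for (r in seq_len(k + 1L)) {
      costs <- costs + seg_cost_vec(starts[r, ], ends[r, ])
      ok <- ok & (ends[r, ] - starts[r, ] + 1L >= min_len)
    }
    costs <- costs + penalty * (k + 1L)
    costs[!ok] <- Inf
    j <- which.min(costs)  # first = lexicographically smallest for this k
    if (costs[j] < best$cost ||
        (costs[j] == best$cost && lex_less(combos[, j], best$breaks))) {
      best <- list(starts = starts[, j], cost = costs[j], breaks = combos[, j])
    }
  }
  best[c("starts", "cost")]
}
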