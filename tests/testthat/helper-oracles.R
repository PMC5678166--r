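# Independent oracle implementations used to validate the package's
# optimised code paths. These deliberately use naive O(n*w) / enumeration
# algorithms and share no code with the implementations they check.

# Naive centred sliding mean with edge truncation.
naive_sliding_mean <- function(x, n_win) {
  half <- (n_win - 1) / 2
  vapply(seq_along(x), function(i) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Naive per-window mean of a series over a closed interval.
naive_window_mean <- function(times, values, centre, half_width) {
  sel <- times >= centre - half_width & times <= centre + half_width
  if (!any(sel)) return(NA_real_)
  mean(values[sel])
}

# Forward-scan jump filter by repeated full passes: drop the later member
# of the first offending pair, restart, until clean.
naive_jump_filter <- function(x, y, threshold) {
  keep <- seq_along(x)
  repeat {
    dropped <- FALSE
    for (i in seq_along(keep)[-1]) {
      d <- sqrt((x[keep[i]] - x[keep[i - 1]])^2 +
                (y[keep[i]] - y[keep[i - 1]])^2)
      if (d > threshold) {
        keep <- keep[-i]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) return(keep)
  }
}

# Kruskal-Wallis H from first principles (mid-ranks + tie correction).
naive_kw_h <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact Kruskal-Wallis permutation p by full enumeration of group
# assignments (small n only).
naive_kw_exact_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  h_obs <- naive_kw_h(groups)
  assigns <- list(seq_along(x))
  split_assign <- function(avail, sizes) {
    if (!length(sizes)) return(list(list()))
    out <- list()
    for (sel in utils::combn(avail, sizes[1], simplify = FALSE)) {
      for (rest in split_assign(setdiff(avail, sel), sizes[-1]))
        out[[length(out) + 1]] <- c(list(sel), rest)
    }
    out
  }
  hs <- vapply(split_assign(seq_along(x), sizes), function(a) {
    naive_kw_h(lapply(a, function(ii) x[ii]))
  }, numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# Partial Mantel statistic via the textbook partial-correlation formula
# (independent of the package's residual-regression route).
naive_partial_mantel_r <- function(a, b, c) {
  lt <- lower.tri(a)
  rab <- cor(a[lt], b[lt]); rac <- cor(a[lt], c[lt]); rbc <- cor(b[lt], c[lt])
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

# Exhaustive partial Mantel p over all n! row/column orders of `a`.
naive_partial_mantel_exhaustive <- function(a, b, c) {
  n <- nrow(a)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  r_obs <- naive_partial_mantel_r(a, b, c)
  rs <- vapply(perms(seq_len(n)), function(p)
    naive_partial_mantel_r(a[p, p], b, c), numeric(1))
  list(R = r_obs, p = mean(rs >= r_obs - 1e-12), n_perm = length(rs))
}

# Brute-force distance from a point to a polygon boundary via dense
# sampling of every edge.
naive_dist_to_ring <- function(px, py, poly, k = 2000) {
  n <- nrow(poly)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    t <- seq(0, 1, length.out = k)
    ex <- poly[i, 1] + t * (poly[j, 1] - poly[i, 1])
    ey <- poly[i, 2] + t * (poly[j, 2] - poly[i, 2])
    best <- min(best, min(sqrt((ex - px)^2 + (ey - py)^2)))
  }
  best
}

# Random symmetric zero-diagonal matrix (distance-like) for Mantel tests.
sym0 <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n)
  m <- m + t(m); diag(m) <- 0
  m
}

# Simple trace constructor for accelerometry tests.
make_trace <- function(ax, ay, az, rate = 40, t0 = 0) {
  accel_trace(t0 + seq_along(ax) / rate, ax, ay, az, rate, "Mtest")
}
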