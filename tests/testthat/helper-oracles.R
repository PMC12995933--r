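# Independent brute-force oracles, deliberately written with naive loops
# so they share no code path with the package implementation.

# two-pass Pearson r between two vectors
naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

naive_correlation_matrix <- function(frames3d, rows, cols) {
  Tn <- dim(frames3d)[3]
  M <- matrix(1, Tn, Tn)
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    if (i == j) next
    M[i, j] <- naive_pearson(as.vector(frames3d[rows, cols, i]),
                             as.vector(frames3d[rows, cols, j]))
  }
  M
}

# Benjamini-Hochberg step-up, written from the definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, p[o[k]] * n / k)
    adj[o[k]] <- running
  }
  adj
}

# polygon area by the cross-product definition, one term at a time
naive_polygon_area <- function(v) {
  n <- nrow(v); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

naive_polygon_perimeter <- function(v) {
  n <- nrow(v); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt((v[i, 1] - v[j, 1])^2 + (v[i, 2] - v[j, 2])^2)
  }
  s
}

# gift-wrapping (Jarvis march) convex hull, independent of grDevices::chull
naive_convex_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (n >= 1) setdiff(seq_len(n), p) else integer(0)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      if (cr < 0 || (cr == 0 &&
          sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2)))
        q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
  }
  pts[hull, , drop = FALSE]
}

# quick builders
rand_stack <- function(h, w, tn, seed, ps = 0.2, dt = 0.4) {
  set.seed(seed)
  image_stack(array(runif(h * w * tn), c(h, w, tn)), ps, dt)
}

regular_ngon <- function(n, radius = 1) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(th), radius * sin(th))
}
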