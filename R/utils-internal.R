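# Internal numerical helpers shared across modules.

# Deterministic child seeds: one root seed split hierarchically so that,
# e.g., filament slot i always sees the same RNG stream regardless of how
# many other slots exist.  Arithmetic stays below 2^53 so doubles are exact;
# result is a valid 32-bit seed.
child_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (id in ids) {
    s <- (s * 69069 + as.numeric(id) * 30269 + 1013904223) %% 2147483647
  }
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 1-D convolution of a matrix along rows (axis = 1) or columns (axis = 2)
# with replicate (clamped-index) boundary handling.
conv_axis <- function(x, k, axis) {
  r <- (length(k) - 1L) / 2L
  n <- dim(x)[axis]
  out <- x * 0
  for (i in seq_along(k)) {
    o <- i - 1L - r
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    out <- out + if (axis == 1L) k[i] * x[idx, , drop = FALSE] else
      k[i] * x[, idx, drop = FALSE]
  }
  out
}

# Separable Gaussian smoothing with replicate padding.  Unlike FFT-based
# blurs this behaves sensibly on images smaller than the kernel support.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  conv_axis(conv_axis(x, k, 1L), k, 2L)
}

# Shift a matrix by (dr, dc), filling vacated cells.
shift_mat <- function(x, dr, dc, fill = 0) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  rsrc <- seq_len(h) - dr; csrc <- seq_len(w) - dc
  rok <- rsrc >= 1 & rsrc <= h; cok <- csrc >= 1 & csrc <= w
  out[rok, cok] <- x[rsrc[rok], csrc[cok]]
  out
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), vectorised over
# the rejection loop; kappa = 0 falls back to the uniform circle.
rvonmises <- function(n, kappa, mu = 0) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rho * z) / (rho + z)
    cc <- kappa * (rho - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    out[need[ok]] <- th[ok]
    need <- need[!ok]
  }
  (out + mu + pi) %% (2 * pi) - pi
}

# Central-difference spatial gradients of a matrix (replicate boundary).
grad_mat <- function(x) {
  gy <- (shift_mat(x, -1, 0, fill = NA) - shift_mat(x, 1, 0, fill = NA)) / 2
  gx <- (shift_mat(x, 0, -1, fill = NA) - shift_mat(x, 0, 1, fill = NA)) / 2
  gy[1, ] <- x[2, ] - x[1, ]; gy[nrow(x), ] <- x[nrow(x), ] - x[nrow(x) - 1, ]
  gx[, 1] <- x[, 2] - x[, 1]; gx[, ncol(x)] <- x[, ncol(x)] - x[, ncol(x) - 1]
  list(gr = gy, gc = gx)
}
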