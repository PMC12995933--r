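test_that("correlation matrix matches hand-computed values on a toy stack", {
  # 3 frames of 4 pixels, written out by hand
  f1 <- c(0.1, 0.4, 0.3, 0.9)
  f2 <- c(0.2, 0.5, 0.1, 0.8)
  f3 <- c(0.9, 0.1, 0.5, 0.2)
  frames <- array(c(f1, f2, f3), c(2, 2, 3))
  st <- image_stack(frames, 0.2, 0.4)
  roi <- list(row0 = 0L, col0 = 0L, side_px = 2L)
  M <- correlation_matrix(st, roi)
  expect_equal(M, naive_correlation_matrix(frames, 1:2, 1:2),
               tolerance = 1e-12)
  expect_equal(diag(M), rep(1, 3))
  expect_equal(M, t(M))
})

test_that("identical and affinely related frames give r = 1", {
  f <- matrix(runif(16), 4)
  frames <- array(c(f, f, 2 * f + 0.1), c(4, 4, 3))
  st <- image_stack(frames, 1, 1)
  M <- correlation_matrix(st, list(row0 = 0L, col0 = 0L, side_px = 4L))
  expect_equal(as.vector(M), rep(1, 9), tolerance = 1e-12)
})

test_that("zero-variance frames are rejected with the frame named", {
  frames <- array(runif(32), c(4, 4, 2))
  frames[, , 2] <- 0.5
  st <- image_stack(frames, 1, 1)
  expect_error(correlation_matrix(st, list(row0 = 0L, col0 = 0L, side_px = 4L)),
               "frame\\(s\\) 2")
})

test_that("lag traces average superdiagonals", {
  # superdiagonals: k=1 -> (0.9, 0.9, 0.8), k=2 -> (0.7, 0.6), k=3 -> 0.5
  M <- diag(4)
  M[1, 2] <- 0.9; M[2, 3] <- 0.9; M[3, 4] <- 0.8
  M[1, 3] <- 0.7; M[2, 4] <- 0.6; M[1, 4] <- 0.5
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  tr <- trace_from_matrix(M, 0.4)
  expect_equal(tr$r_mean, c(mean(c(0.9, 0.9, 0.8)), mean(c(0.7, 0.6)), 0.5))
  expect_equal(tr$lag_s, c(0.4, 0.8, 1.2))
  expect_equal(tr$n_pairs, c(3L, 2L, 1L))

  ones <- matrix(1, 5, 5)
  expect_equal(trace_from_matrix(ones, 1)$r_mean, rep(1, 4))
  expect_error(trace_from_matrix(matrix(1, 2, 3), 1), "square")

  # mean-z aggregation back-transforms the averaged Fisher z
  trz <- trace_from_matrix(M, 0.4, aggregate = "mean_z")
  expect_equal(trz$r_mean[1], tanh(mean(atanh(c(0.9, 0.9, 0.8)))),
               tolerance = 1e-12)
  expect_equal(trz$r_mean[3], 0.5, tolerance = 1e-12)
})

test_that("Fisher z matches atanh and round-trips", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334, tolerance = 1e-10)
  expect_equal(fisher_z_inverse(fisher_z(0.93)), 0.93, tolerance = 1e-12)
  expect_message(z1 <- fisher_z(1), "clamped")
  expect_lt(z1, Inf)
})

test_that("trace normalization divides by z at the smallest lag", {
  tr <- structure(data.frame(roi_id = 1L, lag_s = c(0.4, 0.8),
                             r_mean = c(0.9, 0.5), n_pairs = c(2L, 1L)),
                  class = c("correlation_trace", "data.frame"))
  nt <- normalize_trace(tr)
  expect_identical(nt$z_norm[1], 1)
  expect_equal(nt$z_norm[2], atanh(0.5) / atanh(0.9), tolerance = 1e-9)
  expect_equal(nt$z_norm[2], 0.37312, tolerance = 1e-4)

  # constant trace: z_norm is 1 everywhere
  trc <- tr; trc$r_mean <- c(0.9, 0.9)
  expect_equal(normalize_trace(trc)$z_norm, c(1, 1))

  tr0 <- tr; tr0$r_mean <- c(0, 0.5)
  expect_error(normalize_trace(tr0), "cannot be normalized")
})

test_that("a static noiseless movie yields clamped r = 1 and z_norm = 1", {
  p <- filament_sim_params(width_px = 48, height_px = 48, n_frames = 6,
                           n_filaments = 6, turnover_rate_per_s = 0,
                           noise_sd = 0, seed = 31)
  st <- simulate_filament_movie(p)$stack
  tr <- roi_traces(st, roi_full_frame(st))
  expect_equal(tr$r_mean, rep(1, 5), tolerance = 1e-12)
  expect_equal(tr$z_norm, rep(1, 5))
})

test_that("correlation matrices agree with the brute-force oracle", {
  for (k in 1:10) {
    st <- rand_stack(8, 8, 5, seed = 100 + k)
    M <- correlation_matrix(st, list(row0 = 0L, col0 = 0L, side_px = 8L))
    expect_lt(max(abs(M - naive_correlation_matrix(st$frames, 1:8, 1:8))),
              1e-10)
  }
})

test_that("BH adjustment equals the step-up definition", {
  set.seed(12)
  for (k in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  # all raw p equal: BH is a fixed point
  p <- rep(0.2, 7)
  expect_equal(stats::p.adjust(p, "BH"), p)
})

test_that("identical groups are never flagged and inputs are validated", {
  set.seed(44)
  lags <- seq(0.4, 4, by = 0.4)
  mk <- function(ids, shift = 0) do.call(rbind, lapply(ids, function(i) {
    data.frame(roi_id = i, lag_s = lags,
               z_norm = c(1, exp(-lags[-1]) + rnorm(9, 0, 0.02) + shift))
  }))
  A <- mk(1:6)
  cmp <- compare_groups(A, A)
  expect_false(any(cmp$sig_05))
  expect_false(any(cmp$sig_01))
  expect_true(all(cmp$p_bh >= cmp$p_raw - 1e-15))

  B <- mk(1:6); B$lag_s <- B$lag_s * 2
  expect_error(compare_groups(A, B), "lag grid")
  expect_error(compare_groups(A[A$roi_id == 1, ], A), "2 ROIs")

  # a clear shift is detected
  cmp2 <- compare_groups(A, mk(7:12, shift = 0.5))
  expect_true(any(cmp2$sig_05))
})

test_that("turnover rate orders the decay curves (seed-averaged)", {
  zmean <- function(rate, seed) {
    p <- filament_sim_params(width_px = 64, height_px = 64, n_frames = 40,
                             n_filaments = 10, turnover_rate_per_s = rate,
                             seed = seed)
    st <- enhance_contrast(simulate_filament_movie(p)$stack)
    tr <- roi_traces(st, roi_full_frame(st))
    tr$z_norm
  }
  lo <- rowMeans(sapply(1:6, function(s) zmean(0.02, 600 + s)))
  hi <- rowMeans(sapply(1:6, function(s) zmean(0.15, 700 + s)))
  sel <- 3:39   # lags of at least 3 frames
  expect_true(all(lo[sel] > hi[sel]))
})

test_that("trace tables round-trip through CSV", {
  df <- data.frame(roi_id = rep(1:2, each = 3), group = "g",
                   lag_s = rep(c(0.4, 0.8, 1.2), 2),
                   r_mean = runif(6), z = runif(6), z_norm = runif(6))
  path <- tempfile(fileext = ".csv")
  write_traces(df, path)
  expect_equal(read_traces(path)$z_norm, df$z_norm)
})

test_that("trace aggregation averages ROIs within a unit", {
  tr <- data.frame(roi_id = c(1, 1, 2, 2, 3, 3),
                   movie = c(1, 1, 1, 1, 2, 2),
                   lag_s = rep(c(0.4, 0.8), 3),
                   z_norm = c(1, 0.8, 1, 0.6, 1, 0.4))
  ag <- aggregate_traces(tr, "movie")
  expect_equal(ag$z_norm[ag$roi_id == 1 & ag$lag_s == 0.8], 0.7)
  expect_equal(ag$z_norm[ag$roi_id == 2 & ag$lag_s == 0.8], 0.4)
  expect_equal(nrow(ag), 4)
  expect_error(aggregate_traces(tr, "plant"), "no column")
})
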