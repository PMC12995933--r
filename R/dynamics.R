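#' Pairwise Pearson frame-correlation matrix of one ROI
#'
#' Entry (i, j) is the Pearson correlation between the ROI's pixel vectors
#' of frames i and j; the matrix is symmetric with a unit diagonal.  The
#' correlation between frame pairs is the elementary measurement behind
#' frame-correlation decay: identical frames give r = 1, and r drops as
#' filament turnover rearranges the local pattern.
#'
#' @param stack an [image_stack()].
#' @param roi one row of a `roi_set` (see [make_roi_grid()]).
#' @return `T x T` numeric correlation matrix.
#' @examples
#' st <- image_stack(array(runif(8 * 8 * 4), c(8, 8, 4)), 0.2, 0.4)
#' roi <- list(row0 = 0L, col0 = 0L, side_px = 8L)
#' diag(correlation_matrix(st, roi))
#' @export
correlation_matrix <- function(stack, roi) {
  P <- roi_pixels(stack, roi)           # pixels x frames
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero pixel variance inside ROI at frame(s) ",
         paste(which(sds == 0), collapse = ", "))
  M <- stats::cor(P)
  diag(M) <- 1
  M
}

#' Correlation-decay trace: mean r per time lag
#'
#' Averages the k-th superdiagonal of a frame-correlation matrix to obtain
#' the mean Pearson r at lag `k * frame_interval_s`, for k = 1 .. T-1
#' (lag 0 is excluded as trivially r = 1).
#'
#' With the default `aggregate = "mean_r"` the raw correlations of a
#' superdiagonal are averaged and the mean is later transformed to
#' Fisher z; the alternative `"mean_z"` averages the Fisher z of the
#' individual pairs and back-transforms, which down-weights high-r pairs
#' less.  The two differ only slightly for typical traces.
#'
#' @param mat square symmetric correlation matrix (T >= 2).
#' @param frame_interval_s frame interval in seconds.
#' @param roi_id optional ROI identifier carried into the result.
#' @param aggregate per-lag aggregation, `"mean_r"` (default) or
#'   `"mean_z"`.
#' @return A `correlation_trace`: data.frame with columns `roi_id`,
#'   `lag_s`, `r_mean`, `n_pairs` (lag k has T - k frame pairs).
#' @export
trace_from_matrix <- function(mat, frame_interval_s, roi_id = NA_integer_,
                              aggregate = c("mean_r", "mean_z")) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("'mat' must be a square matrix")
  aggregate <- match.arg(aggregate)
  Tn <- nrow(mat)
  if (Tn < 2L) stop("need at least 2 frames")
  agg <- if (aggregate == "mean_r") mean else
    function(v) tanh(mean(suppressMessages(fisher_z(v))))
  r_mean <- vapply(seq_len(Tn - 1L), function(k)
    agg(mat[cbind(seq_len(Tn - k), seq_len(Tn - k) + k)]), 0)
  structure(data.frame(roi_id = roi_id,
                       lag_s = seq_len(Tn - 1L) * frame_interval_s,
                       r_mean = r_mean,
                       n_pairs = Tn - seq_len(Tn - 1L)),
            class = c("correlation_trace", "data.frame"))
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` is `atanh(r)` after clamping r to +/-(1 - 1e-7) (a message
#' reports how many values were clamped); `fisher_z_inverse()` is
#' `tanh(z)`.  The transform is variance-stabilizing for statistics on
#' correlation coefficients.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param z Fisher z value(s).
#' @return numeric vector of the same length.
#' @examples
#' fisher_z(0.5)              # 0.5493061
#' fisher_z_inverse(fisher_z(0.93))
#' @export
fisher_z <- function(r) {
  bound <- 1 - 1e-7
  n_clamped <- sum(abs(r) > bound, na.rm = TRUE)
  if (n_clamped > 0)
    message("fisher_z: clamped ", n_clamped, " value(s) to +/-", bound)
  atanh(pmin(pmax(r, -bound), bound))
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Normalize a correlation trace by its Fisher z at the smallest lag
#'
#' Divides the Fisher z of the mean r at every lag by the value at the
#' smallest lag, so traces from ROIs with different baseline correlations
#' become comparable: the normalized trace starts at exactly 1 and its
#' decay reflects relative loss of pattern similarity.
#'
#' @param trace a `correlation_trace` from [trace_from_matrix()].
#' @param group_label optional group label carried into the result.
#' @return A `normalized_trace`: data.frame with columns `roi_id`,
#'   `group`, `lag_s`, `r_mean`, `z`, `z_norm` (`z_norm[1]` is exactly 1).
#' @export
normalize_trace <- function(trace, group_label = NA_character_) {
  stopifnot(inherits(trace, "data.frame"), nrow(trace) >= 1L)
  z <- suppressMessages(fisher_z(trace$r_mean))
  if (z[1L] == 0)
    stop("Fisher z at the smallest lag is 0; ROI ", trace$roi_id[1L],
         " cannot be normalized and should be excluded")
  z_norm <- z / z[1L]
  z_norm[1L] <- 1
  structure(data.frame(roi_id = trace$roi_id, group = group_label,
                       lag_s = trace$lag_s, r_mean = trace$r_mean,
                       z = z, z_norm = z_norm),
            class = c("normalized_trace", "data.frame"))
}

#' Normalized correlation-decay traces for every kept ROI of a stack
#'
#' Convenience wrapper: for each kept ROI, computes the frame-correlation
#' matrix, the per-lag mean-r trace and the Fisher-z-normalized trace, and
#' stacks the results in one tidy table.  ROIs whose pixel variance
#' vanishes in some frame, or whose lag-1 Fisher z is zero, are skipped
#' with a message (mirroring manual exclusion of unusable regions).
#'
#' @param stack a preprocessed [image_stack()].
#' @param rois a `roi_set`.
#' @param group_label optional group label attached to every trace.
#' @param plant_id,replicate_id optional experimental-unit identifiers
#'   recorded per trace row, so hierarchical models can be fitted
#'   externally.
#' @param aggregate per-lag aggregation passed to [trace_from_matrix()].
#' @return data.frame with columns `roi_id`, `plant_id`, `replicate_id`,
#'   `group`, `lag_s`, `r_mean`, `z`, `z_norm`.
#' @export
roi_traces <- function(stack, rois, group_label = NA_character_,
                       plant_id = NA, replicate_id = NA,
                       aggregate = c("mean_r", "mean_z")) {
  aggregate <- match.arg(aggregate)
  out <- lapply(which(rois$kept), function(i) {
    roi <- rois[i, ]
    tr <- tryCatch(
      normalize_trace(trace_from_matrix(correlation_matrix(stack, roi),
                                        stack$frame_interval_s,
                                        roi_id = roi$roi_id,
                                        aggregate = aggregate),
                      group_label = group_label),
      error = function(e) {
        message("roi_traces: skipping ROI ", roi$roi_id, ": ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(tr)) {
      tr$plant_id <- plant_id
      tr$replicate_id <- replicate_id
    }
    tr
  })
  do.call(rbind, out)
}

# Welch two-sample two-tailed t-test returning (diff, p), with a guard for
# degenerate zero-variance groups (identical constants -> p = 1).
welch_p <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  n1 <- length(x); n2 <- length(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(c(diff = m1 - m2, p = if (m1 == m2) 1 else 0))
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(diff = m1 - m2, p = 2 * stats::pt(-abs(tstat), df))
}

#' Per-lag group comparison of normalized correlation traces
#'
#' For every time lag, compares `z_norm` across ROIs between two groups by
#' a two-tailed Welch two-sample t-test, then applies Benjamini-Hochberg
#' correction jointly across all lags of the comparison.  Group means and
#' pointwise 95% CIs are also returned back-transformed through `tanh` to
#' the r scale for plotting.
#'
#' @param tracesA,tracesB tidy trace tables (from [roi_traces()] or
#'   [normalize_trace()]) with columns `roi_id`, `lag_s`, `z_norm`; at
#'   least 2 ROIs per group, identical lag grids.
#' @param alpha_levels significance levels for the flag columns
#'   (default 0.05 and 0.01).
#' @return A `lag_comparison`: data.frame with columns `lag_s`, `mean_A`,
#'   `mean_B` (mean z_norm), `diff`, `r_A`, `r_lo_A`, `r_hi_A`, `r_B`,
#'   `r_lo_B`, `r_hi_B` (tanh back-transformed mean and 95% CI), `p_raw`,
#'   `p_bh`, and one logical `sig_<level>` column per alpha level.
#' @export
compare_groups <- function(tracesA, tracesB, alpha_levels = c(0.05, 0.01)) {
  lagsA <- sort(unique(tracesA$lag_s)); lagsB <- sort(unique(tracesB$lag_s))
  if (length(lagsA) != length(lagsB) || any(lagsA != lagsB))
    stop("the two groups must share a common lag grid")
  nA <- length(unique(tracesA$roi_id)); nB <- length(unique(tracesB$roi_id))
  if (nA < 2L || nB < 2L) stop("need at least 2 ROIs per group")

  per_lag <- function(tr, lag) tr$z_norm[tr$lag_s == lag]
  res <- t(vapply(lagsA, function(l) {
    zA <- per_lag(tracesA, l); zB <- per_lag(tracesB, l)
    wp <- welch_p(zA, zB)
    ci <- function(z) {
      m <- mean(z); s <- stats::sd(z) / sqrt(length(z))
      q <- stats::qt(0.975, length(z) - 1L)
      c(m, m - q * s, m + q * s)
    }
    c(mean_A = mean(zA), mean_B = mean(zB), wp["diff"],
      ciA = ci(zA), ciB = ci(zB), p_raw = wp[["p"]])
  }, numeric(10)))

  out <- data.frame(lag_s = lagsA,
                    mean_A = res[, "mean_A"], mean_B = res[, "mean_B"],
                    diff = res[, "diff"],
                    r_A = tanh(res[, "ciA1"]), r_lo_A = tanh(res[, "ciA2"]),
                    r_hi_A = tanh(res[, "ciA3"]),
                    r_B = tanh(res[, "ciB1"]), r_lo_B = tanh(res[, "ciB2"]),
                    r_hi_B = tanh(res[, "ciB3"]),
                    p_raw = res[, "p_raw"])
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  for (a in alpha_levels)
    out[[paste0("sig_", sub("^0\\.", "", format(a)))]] <- out$p_bh < a
  structure(out, class = c("lag_comparison", "data.frame"))
}

#' Aggregate normalized traces to a higher experimental unit
#'
#' Averages `z_norm` per time lag within each level of a grouping column
#' (for example `movie` or `plant_id`), returning one trace per unit with
#' `roi_id` set to the unit label.  [compare_groups()] assumes its traces
#' are exchangeable units: when one movie or plant contributes several
#' ROIs, the ROIs share a filament realization and the per-lag t-test
#' would pseudo-replicate it, so aggregate to the independent unit first
#' — the same principle as the plant-level aggregation in
#' [compare_shape_groups()].
#'
#' @param traces tidy trace table with `lag_s`, `z_norm` and the grouping
#'   column.
#' @param by name of the grouping column.
#' @return data.frame with columns `roi_id` (the unit), `lag_s`,
#'   `z_norm`.
#' @export
aggregate_traces <- function(traces, by = "movie") {
  if (!by %in% names(traces)) stop("no column '", by, "' in traces")
  a <- stats::aggregate(traces$z_norm,
                        by = list(unit = traces[[by]],
                                  lag_s = traces$lag_s), FUN = mean)
  data.frame(roi_id = a$unit, lag_s = a$lag_s, z_norm = a$x)
}

#' Write / read tidy trace tables as CSV
#' @param traces a tidy trace table (e.g. from [roi_traces()]).
#' @param path CSV file path.
#' @return [write_traces()]: `path` invisibly; [read_traces()]: data.frame.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) utils::read.csv(path)
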