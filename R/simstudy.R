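# Reusable simulation-study building blocks: multi-movie group sampling
# for dynamics comparisons, single-ROI helpers and deterministic line
# fixtures for anisotropy validation.

#' Single ROI covering a whole stack frame
#'
#' @param stack an [image_stack()].
#' @return a one-row `roi_set` spanning the largest centred square.
#' @export
roi_full_frame <- function(stack) {
  d <- dim(stack$frames)
  side <- min(d[1:2])
  structure(data.frame(roi_id = 1L,
                       row0 = as.integer((d[1] - side) %/% 2),
                       col0 = as.integer((d[2] - side) %/% 2),
                       side_px = as.integer(side), kept = TRUE),
            class = c("roi_set", "data.frame"))
}

#' Simulate one experimental group of correlation-decay traces
#'
#' Emulates the sampling structure of a live-imaging experiment: a group
#' is a set of independently simulated movies ("plants"), each
#' contributing a few grid ROIs.  Sampling ROIs across independent movies
#' keeps the per-ROI normalized traces approximately exchangeable, which
#' a per-lag t-test across ROIs requires; pooling many ROIs from a single
#' movie would pseudo-replicate one filament realization.
#'
#' @param turnover_rate_per_s filament turnover rate of the group.
#' @param seed root seed (each movie uses `seed + movie index`).
#' @param group_label label attached to the traces.
#' @param n_movies independent movies per group.
#' @param rois_per_movie grid ROIs retained per movie.
#' @param width_px,n_filaments,noise_sd,n_frames generator settings.
#' @param radius_px rolling-ball radius of the preprocessing step.
#' @param spacing_um ROI grid pitch.
#' @return tidy trace table (see [roi_traces()]) with movie-unique
#'   `roi_id`s and a `movie` column.
#' @export
simulate_group_traces <- function(turnover_rate_per_s, seed,
                                  group_label = NA_character_,
                                  n_movies = 5L, rois_per_movie = 5L,
                                  width_px = 112L, n_filaments = 15L,
                                  noise_sd = 0.02, n_frames = 149L,
                                  radius_px = 25L, spacing_um = 5.6) {
  out <- vector("list", n_movies)
  for (m in seq_len(n_movies)) {
    p <- filament_sim_params(width_px = width_px, height_px = width_px,
                             n_frames = n_frames,
                             n_filaments = n_filaments,
                             turnover_rate_per_s = turnover_rate_per_s,
                             noise_sd = noise_sd, seed = seed + m)
    st <- preprocess_stack(simulate_filament_movie(p)$stack,
                           radius_px = radius_px)
    rois <- make_roi_grid(st, spacing_um = spacing_um, seed = seed + m)
    tr <- roi_traces(st, rois, group_label)
    ids <- unique(tr$roi_id)
    ids <- ids[seq_len(min(rois_per_movie, length(ids)))]
    tr <- tr[tr$roi_id %in% ids, ]
    tr$movie <- m
    tr$roi_id <- tr$roi_id + 1000L * m
    out[[m]] <- tr
  }
  do.call(rbind, out)
}

#' Deterministic line fixtures for anisotropy validation
#'
#' `fixture_parallel_lines()` renders equally spaced horizontal lines (a
#' perfectly aligned network, expected coherence near 1);
#' `fixture_random_lines()` renders many short lines with orientations
#' uniform on `[0, pi)` (an isotropic network, expected coherence near 0
#' when the tensor window exceeds the line spacing).  Both are blurred
#' with a Gaussian PSF.
#'
#' @param size image side in pixels.
#' @param spacing_px line spacing (parallel fixture).
#' @param n_lines,half_len_px number and half-length of lines (isotropic
#'   fixture).
#' @param psf_sigma_px Gaussian blur applied after rasterization.
#' @param seed RNG seed (isotropic fixture).
#' @return numeric matrix on the `[0, 1]` scale.
#' @export
fixture_parallel_lines <- function(size = 128L, spacing_px = 12L,
                                   psf_sigma_px = 1.5) {
  f <- matrix(0, size, size)
  margin <- max(8L, spacing_px %/% 2L)
  for (r in seq(margin, size - margin, by = spacing_px))
    f[r, margin:(size - margin)] <- 1
  clamp01(gauss_blur(f, psf_sigma_px))
}

#' @rdname fixture_parallel_lines
#' @export
fixture_random_lines <- function(size = 160L, n_lines = 200L,
                                 half_len_px = 6, psf_sigma_px = 1.5,
                                 seed = 1L) {
  set.seed(child_seed(seed, 5L))
  f <- matrix(0, size, size)
  for (k in seq_len(n_lines)) {
    x0 <- stats::runif(1, 2 + half_len_px, size - half_len_px - 1)
    y0 <- stats::runif(1, 2 + half_len_px, size - half_len_px - 1)
    th <- stats::runif(1, 0, pi)
    tt <- seq(-half_len_px, half_len_px, by = 0.5)
    xs <- round(x0 + tt * cos(th)); ys <- round(y0 + tt * sin(th))
    ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
    f[cbind(ys[ok], xs[ok])] <- 1
  }
  clamp01(gauss_blur(f, psf_sigma_px))
}
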