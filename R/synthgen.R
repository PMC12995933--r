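#' Parameters for the synthetic cortical-filament movie generator
#'
#' Describes a Lifeact-GFP-like cortical actin movie: static filaments that
#' stochastically die with an exponential waiting time and are immediately
#' replaced by a freshly sampled filament (so the expected filament count is
#' stationary and frame-correlation decay reflects turnover only), a
#' bundled subpopulation carrying an intensity multiplier, Gaussian PSF
#' blur, multiplicative exponential photobleaching and additive Gaussian
#' noise.  Defaults mirror a typical spinning-disc acquisition of cotyledon
#' epidermis: 149 frames at 400 ms.
#'
#' @param width_px,height_px image size in pixels (>= 1).
#' @param n_frames number of time points (>= 1).
#' @param pixel_size_um pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param n_filaments expected number of filaments alive at any time (>= 1).
#' @param persistence_px directional persistence of filament paths: the
#'   von Mises concentration of the per-pixel-step heading perturbation
#'   (large = straight filaments).
#' @param turnover_rate_per_s exponential death/rebirth rate per filament
#'   (1/s, >= 0; 0 = immortal filaments).
#' @param bundling_factor intensity multiplier (>= 1) applied to the
#'   bundled subpopulation; a proxy for filament bundling.
#' @param bundling_fraction fraction of filaments carrying the multiplier.
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels (> 0).
#' @param noise_sd additive Gaussian noise SD on the 0-1 intensity scale.
#' @param bleach_rate_per_frame photobleaching rate: frame `t` (0-based) is
#'   scaled by `exp(-bleach_rate_per_frame * t)` before noise.
#' @param length_range_px filament contour length range in pixels; lengths
#'   are drawn uniformly from this interval.
#' @param orientation_kappa von Mises concentration of initial filament
#'   headings around 0 (horizontal); 0 = isotropic orientations.
#' @param filament_intensity line density (intensity per pixel of filament
#'   length, before PSF blur) of an unbundled filament.
#' @param seed root RNG seed; split hierarchically per filament slot and
#'   per frame, so the noise stream is independent of the geometry stream.
#'
#' @return A validated list of class `filament_sim_params`.
#' @seealso [simulate_filament_movie()]
#' @export
filament_sim_params <- function(width_px = 192L, height_px = 192L,
                                n_frames = 149L, pixel_size_um = 0.2,
                                frame_interval_s = 0.4, n_filaments = 40L,
                                persistence_px = 40, turnover_rate_per_s = 0.05,
                                bundling_factor = 1, bundling_fraction = 0.3,
                                psf_sigma_px = 1.5, noise_sd = 0.02,
                                bleach_rate_per_frame = 0,
                                length_range_px = c(40, 120),
                                orientation_kappa = 0,
                                filament_intensity = 0.6, seed = 1L) {
  p <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
            n_frames = as.integer(n_frames),
            pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s,
            n_filaments = as.integer(n_filaments),
            persistence_px = persistence_px,
            turnover_rate_per_s = turnover_rate_per_s,
            bundling_factor = bundling_factor,
            bundling_fraction = bundling_fraction,
            psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
            bleach_rate_per_frame = bleach_rate_per_frame,
            length_range_px = as.numeric(length_range_px),
            orientation_kappa = orientation_kappa,
            filament_intensity = filament_intensity, seed = as.integer(seed))
  with(p, {
    if (width_px < 1L || height_px < 1L) stop("image dimensions must be >= 1")
    if (n_frames < 1L) stop("'n_frames' must be >= 1")
    if (n_filaments < 1L) stop("'n_filaments' must be >= 1")
    if (pixel_size_um <= 0 || frame_interval_s <= 0)
      stop("pixel size and frame interval must be positive")
    if (persistence_px <= 0) stop("'persistence_px' must be positive")
    if (turnover_rate_per_s < 0 || noise_sd < 0 || bleach_rate_per_frame < 0)
      stop("rates and noise must be non-negative")
    if (bundling_factor < 1) stop("'bundling_factor' must be >= 1")
    if (bundling_fraction < 0 || bundling_fraction > 1)
      stop("'bundling_fraction' must be in [0, 1]")
    if (psf_sigma_px <= 0) stop("'psf_sigma_px' must be positive")
    if (length(length_range_px) != 2L || any(length_range_px <= 0) ||
        length_range_px[1] > length_range_px[2])
      stop("'length_range_px' must be an increasing positive pair")
  })
  structure(p, class = "filament_sim_params")
}

# Sample one filament path (persistent random walk, 1-px steps) and render
# it, PSF-blurred, into a sparse (index, value) pair on the full canvas.
# Uses the current RNG stream; returns NULL when the blurred footprint
# falls entirely outside the image.
render_filament <- function(p, bundled) {
  L <- stats::runif(1, p$length_range_px[1], p$length_range_px[2])
  m <- max(2L, as.integer(ceiling(L)))
  x0 <- stats::runif(1, 1, p$width_px)
  y0 <- stats::runif(1, 1, p$height_px)
  h0 <- if (p$orientation_kappa > 0)
    rvonmises(1, p$orientation_kappa) else stats::runif(1, -pi, pi)
  dh <- rvonmises(m - 1L, p$persistence_px)
  headings <- h0 + c(0, cumsum(dh))
  xs <- x0 + c(0, cumsum(cos(headings)))
  ys <- y0 + c(0, cumsum(sin(headings)))
  # resample at 0.5-px spacing for smooth deposition
  t0 <- seq_len(m + 1L)
  tq <- seq(1, m + 1L, by = 0.5)
  xq <- stats::approx(t0, xs, tq)$y
  yq <- stats::approx(t0, ys, tq)$y
  w <- 0.5 * p$filament_intensity * if (bundled) p$bundling_factor else 1

  pad <- as.integer(ceiling(3 * p$psf_sigma_px)) + 1L
  r0 <- floor(min(yq)) - pad
  c0 <- floor(min(xq)) - pad
  ph <- as.integer(ceiling(max(yq)) + pad - r0 + 1L)
  pw <- as.integer(ceiling(max(xq)) + pad - c0 + 1L)
  patch <- matrix(0, ph, pw)
  rr <- yq - r0 + 1; cc <- xq - c0 + 1
  rf <- floor(rr); cf <- floor(cc)
  ar <- rr - rf; ac <- cc - cf
  idx <- c((cf - 1) * ph + rf, cf * ph + rf,
           (cf - 1) * ph + rf + 1, cf * ph + rf + 1)
  val <- w * c((1 - ar) * (1 - ac), (1 - ar) * ac,
               ar * (1 - ac), ar * ac)
  add <- rowsum(val, idx)
  patch[as.integer(rownames(add))] <- add
  patch <- gauss_blur(patch, p$psf_sigma_px)

  # clip patch to the image and convert to full-canvas linear indices
  rows <- r0 + seq_len(ph) - 1L; cols <- c0 + seq_len(pw) - 1L
  rok <- rows >= 1L & rows <= p$height_px
  cok <- cols >= 1L & cols <= p$width_px
  if (!any(rok) || !any(cok)) return(NULL)
  sub <- patch[rok, cok, drop = FALSE]
  keep <- which(sub > 1e-9)
  if (length(keep) == 0L) return(NULL)
  kr <- ((keep - 1L) %% nrow(sub)) + 1L
  kc <- ((keep - 1L) %/% nrow(sub)) + 1L
  full <- (cols[cok][kc] - 1L) * p$height_px + rows[rok][kr]
  list(idx = full, val = sub[keep])
}

#' Simulate a synthetic cortical filament movie
#'
#' Runs the filament birth/death process described in
#' [filament_sim_params()] and renders every frame.  Filaments are static
#' while alive; a filament dies with exponential waiting time
#' `Exp(turnover_rate_per_s)` and is replaced, at the instant of death, by
#' a newly sampled filament in the same slot, keeping the expected count
#' constant.  Rendering order per frame: sum of PSF-blurred filament
#' images, multiplicative bleach `exp(-bleach_rate_per_frame * t)`,
#' additive Gaussian noise, clipping to `[0, 1]`.
#'
#' Identical parameters (including `seed`) give bit-identical output.  The
#' per-slot RNG streams are independent, so changing `n_filaments` does not
#' reshuffle existing filaments, and the noise stream is independent of the
#' geometry, so toggling `bleach_rate_per_frame` leaves both geometry and
#' noise unchanged.
#'
#' @param params a [filament_sim_params()] object.
#' @return list with elements:
#'   * `stack`: the rendered [image_stack()];
#'   * `truth`: ground truth — `filaments` (data.frame: `filament_id`,
#'     `slot`, `birth_s`, `death_s`, `lifetime_s`, `birth_frame`,
#'     `death_frame`, `bundled`; death times are recorded uncensored, even
#'     past the end of the movie), `paths` (list of n x 2 matrices of path
#'     vertices in pixel coordinates) and `params`.
#' @examples
#' sim <- simulate_filament_movie(filament_sim_params(
#'   width_px = 64, height_px = 64, n_frames = 5, n_filaments = 5, seed = 7))
#' dim(sim$stack$frames)
#' @export
simulate_filament_movie <- function(params) {
  stopifnot(inherits(params, "filament_sim_params"))
  p <- params
  dt <- p$frame_interval_s
  t_end <- (p$n_frames - 1L) * dt
  rate <- p$turnover_rate_per_s

  # exactly this many slots carry the bundling multiplier (deterministic
  # fraction, so the bundled:unbundled mixture is identical across seeds)
  n_bundled <- round(p$bundling_fraction * p$n_filaments)
  inst <- list(); paths <- list(); k <- 0L
  for (slot in seq_len(p$n_filaments)) {
    set.seed(child_seed(p$seed, 1L, slot))
    t_now <- 0
    bundled <- slot <= n_bundled
    repeat {
      life <- if (rate > 0) stats::rexp(1, rate) else Inf
      spr <- render_filament(p, bundled)
      k <- k + 1L
      inst[[k]] <- list(slot = slot, birth = t_now, death = t_now + life,
                        bundled = bundled, sparse = spr)
      t_now <- t_now + life
      if (t_now > t_end) break
    }
  }

  hw <- p$height_px * p$width_px
  frames <- array(0, c(p$height_px, p$width_px, p$n_frames))
  births <- vapply(inst, `[[`, 0, "birth")
  deaths <- vapply(inst, `[[`, 0, "death")
  for (f in seq_len(p$n_frames)) {
    tf <- (f - 1L) * dt
    canvas <- numeric(hw)
    for (i in which(births <= tf & tf < deaths)) {
      s <- inst[[i]]$sparse
      if (!is.null(s)) canvas[s$idx] <- canvas[s$idx] + s$val
    }
    canvas <- canvas * exp(-p$bleach_rate_per_frame * (f - 1L))
    if (p$noise_sd > 0) {
      set.seed(child_seed(p$seed, 2L, f))
      canvas <- canvas + stats::rnorm(hw, 0, p$noise_sd)
    }
    frames[, , f] <- clamp01(matrix(canvas, p$height_px, p$width_px))
  }

  fil <- data.frame(
    filament_id = seq_along(inst),
    slot = vapply(inst, `[[`, 0L, "slot"),
    birth_s = births, death_s = deaths,
    lifetime_s = deaths - births,
    birth_frame = ceiling(births / dt) + 1L,
    death_frame = ifelse(is.finite(deaths), ceiling(deaths / dt) + 1L, NA),
    bundled = vapply(inst, `[[`, TRUE, "bundled"))

  list(stack = image_stack(frames, p$pixel_size_um, p$frame_interval_s),
       truth = list(filaments = fil, params = p))
}

#' Parameters for the lobed-cell mosaic generator
#'
#' Describes a mosaic of non-overlapping pavement-cell-like cells whose
#' boundaries follow `r(theta) = R * (1 + a * sin(m * theta + phi))` with a
#' random per-cell phase `phi`: `R` is the base radius, `m` the lobe count
#' and `a` the relative lobe amplitude.  `a = 0` gives discs; increasing
#' `a` deepens lobes, lowering circularity and solidity.
#'
#' @param n_cells number of cells (>= 1).
#' @param base_radius_um base radius `R` in micrometres (> 0).
#' @param lobe_count angular frequency `m` (integer >= 0).
#' @param lobe_amplitude relative radial modulation `a`, in `[0, 0.9]`
#'   (kept below 1 so the boundary never self-intersects).
#' @param pixel_size_um pixel size of the rasterized mask (> 0).
#' @param seed root RNG seed (per-cell phases use independent substreams).
#' @return A validated list of class `lobed_cell_params`.
#' @seealso [generate_lobed_cells()]
#' @export
lobed_cell_params <- function(n_cells = 20L, base_radius_um = 15,
                              lobe_count = 6L, lobe_amplitude = 0.3,
                              pixel_size_um = 0.3, seed = 1L) {
  p <- list(n_cells = as.integer(n_cells), base_radius_um = base_radius_um,
            lobe_count = as.integer(lobe_count),
            lobe_amplitude = lobe_amplitude,
            pixel_size_um = pixel_size_um, seed = as.integer(seed))
  with(p, {
    if (n_cells < 1L) stop("'n_cells' must be >= 1")
    if (base_radius_um <= 0 || pixel_size_um <= 0)
      stop("radius and pixel size must be positive")
    if (lobe_count < 0L) stop("'lobe_count' must be >= 0")
    if (lobe_amplitude < 0 || lobe_amplitude >= 1)
      stop("'lobe_amplitude' must be in [0, 1); values > 0.9 are rejected")
    if (lobe_amplitude > 0.9) stop("'lobe_amplitude' must be <= 0.9")
  })
  structure(p, class = "lobed_cell_params")
}

#' Generate a label mosaic of lobed cells with exact ground-truth polygons
#'
#' Cells are laid out on a grid with a pitch that guarantees the rasterized
#' cells cannot touch.  Each cell's analytic boundary polygon (720 vertices,
#' micrometre coordinates) is stored as ground truth, so raster
#' morphometrics can be validated against an exact shoelace oracle.
#'
#' @param params a [lobed_cell_params()] object.
#' @return list with elements:
#'   * `mask`: integer label matrix (0 = background, cell `i` has label `i`);
#'   * `truth`: `polygons` (list of 720 x 2 vertex matrices, micrometres),
#'     `centers_um`, `phases` and `params`.
#' @examples
#' mos <- generate_lobed_cells(lobed_cell_params(n_cells = 4, seed = 2))
#' table(mos$mask > 0)
#' @export
generate_lobed_cells <- function(params) {
  stopifnot(inherits(params, "lobed_cell_params"))
  p <- params
  R <- p$base_radius_um; a <- p$lobe_amplitude; m <- p$lobe_count
  ps <- p$pixel_size_um
  ncols <- ceiling(sqrt(p$n_cells))
  nrows <- ceiling(p$n_cells / ncols)
  pitch <- 2 * R * (1 + a) * 1.08 + 2 * ps
  W <- as.integer(ceiling(ncols * pitch / ps))
  H <- as.integer(ceiling(nrows * pitch / ps))
  mask <- matrix(0L, H, W)

  nv <- 720L
  th <- (seq_len(nv) - 1L) * 2 * pi / nv
  polys <- vector("list", p$n_cells)
  centers <- matrix(0, p$n_cells, 2)
  phases <- numeric(p$n_cells)
  for (i in seq_len(p$n_cells)) {
    gi <- (i - 1L) %/% ncols; gj <- (i - 1L) %% ncols
    cx <- (gj + 0.5) * pitch; cy <- (gi + 0.5) * pitch
    set.seed(child_seed(p$seed, 3L, i))
    phi <- stats::runif(1, 0, 2 * pi)
    rad <- R * (1 + a * sin(m * th + phi))
    polys[[i]] <- cbind(x_um = cx + rad * cos(th), y_um = cy + rad * sin(th))
    centers[i, ] <- c(cx, cy); phases[i] <- phi

    rmax <- R * (1 + a)
    cpx <- (max(1, floor((cx - rmax) / ps))):(min(W, ceiling((cx + rmax) / ps)))
    rpx <- (max(1, floor((cy - rmax) / ps))):(min(H, ceiling((cy + rmax) / ps)))
    xg <- (cpx - 0.5) * ps - cx
    yg <- (rpx - 0.5) * ps - cy
    dx <- matrix(xg, length(rpx), length(cpx), byrow = TRUE)
    dy <- matrix(yg, length(rpx), length(cpx))
    rr <- sqrt(dx^2 + dy^2)
    tt <- atan2(dy, dx)
    inside <- rr <= R * (1 + a * sin(m * tt + phi))
    sub <- mask[rpx, cpx]
    if (any(sub[inside] != 0L)) stop("internal error: overlapping cells")
    sub[inside] <- i
    mask[rpx, cpx] <- sub
  }
  list(mask = mask,
       truth = list(polygons = polys, centers_um = centers, phases = phases,
                    params = p))
}

#' Write generator ground truth to plain-text files
#'
#' The parameter set and tabular ground truth go to JSON; the per-filament
#' table or per-cell polygon vertices go to CSV.
#'
#' @param truth the `truth` element returned by [simulate_filament_movie()]
#'   or [generate_lobed_cells()].
#' @param json_path,csv_path output file paths (either may be `NULL`).
#' @return invisibly, a list of the paths written.
#' @export
write_ground_truth <- function(truth, json_path = NULL, csv_path = NULL) {
  is_movie <- !is.null(truth$filaments)
  tab <- if (is_movie) truth$filaments else {
    do.call(rbind, lapply(seq_along(truth$polygons), function(i)
      data.frame(cell_id = i, truth$polygons[[i]])))
  }
  if (!is.null(json_path)) {
    obj <- list(params = unclass(truth$params))
    obj[[if (is_movie) "filaments" else "polygons"]] <- tab
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(list(json = json_path, csv = csv_path))
}
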