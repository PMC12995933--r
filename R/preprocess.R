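#' Rolling-ball background subtraction
#'
#' Estimates a smooth background for every frame as the grayscale
#' morphological opening of the frame with a disc structuring element of
#' the given radius, and subtracts it.  A flat background of any level is
#' removed exactly; features narrower than the disc (filaments, puncta)
#' pass through essentially unchanged; the output is non-negative, and the
#' operation is invariant to an additive constant offset.  This is the
#' opening formulation of the classic rolling-ball correction; it does not
#' replicate the ImageJ paraboloid variant bit-for-bit.
#'
#' @param stack an [image_stack()].
#' @param radius_px disc radius in pixels (>= 1, < min(H, W)).
#' @return an `image_stack` of identical shape.
#' @examples
#' st <- image_stack(matrix(0.3, 32, 32), 0.2, 0.4)
#' max(subtract_background(st, 5)$frames)  # flat background -> 0
#' @export
subtract_background <- function(stack, radius_px) {
  stopifnot(inherits(stack, "image_stack"))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("'radius_px' must be >= 1")
  d <- dim(stack$frames)
  if (radius_px >= min(d[1:2]))
    stop("'radius_px' must be smaller than the image")
  brush <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  out <- stack$frames
  for (t in seq_len(d[3])) {
    fr <- stack$frames[, , t]
    bg <- EBImage::opening(fr, brush)
    out[, , t] <- pmax(fr - bg, 0)
  }
  image_stack(out, stack$pixel_size_um, stack$frame_interval_s)
}

#' Linear contrast enhancement across the full dynamic range
#'
#' Applies one affine map, computed from the global (whole-stack) minimum
#' and maximum, sending the stack onto `[0, 1]`.  Using the global rather
#' than per-frame extrema preserves relative intensities across frames, so
#' photobleaching is still present afterwards and can be corrected by
#' [correct_bleaching()].
#'
#' @param stack an [image_stack()]; must not be constant.
#' @return an `image_stack` with global min 0 and max 1.
#' @export
enhance_contrast <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  if (hi <= lo) stop("constant stack: contrast stretch is undefined")
  image_stack((stack$frames - lo) / (hi - lo),
              stack$pixel_size_um, stack$frame_interval_s)
}

#' Photobleaching correction by histogram matching
#'
#' Remaps every frame's empirical intensity distribution onto the
#' reference frame's distribution by monotone quantile matching: pixels
#' are ranked within their frame and assigned the reference frame's order
#' statistics.  Because all frames have the same pixel count the corrected
#' frame is an exact rearrangement of the reference values, so per-frame
#' means and histograms match the reference exactly; within-frame rank
#' order is preserved.  The reference frame itself is returned unchanged.
#'
#' @param stack an [image_stack()].
#' @param reference_frame index of the reference frame (default 1, the
#'   frame with least accumulated bleach).
#' @return an `image_stack` of identical shape.
#' @export
correct_bleaching <- function(stack, reference_frame = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  Tn <- n_frames(stack)
  reference_frame <- as.integer(reference_frame)
  if (reference_frame < 1L || reference_frame > Tn)
    stop("'reference_frame' out of range")
  ref_sorted <- sort(as.vector(stack$frames[, , reference_frame]))
  out <- stack$frames
  for (t in seq_len(Tn)) {
    if (t == reference_frame) next
    v <- as.vector(stack$frames[, , t])
    o <- order(v)
    v[o] <- ref_sorted
    out[, , t] <- v
  }
  image_stack(out, stack$pixel_size_um, stack$frame_interval_s)
}

#' Randomly positioned square ROI grid
#'
#' Lays a regular grid of pitch `spacing_um` over the image with an origin
#' drawn uniformly in `[0, spacing_px)^2` (seeded), and centres one square
#' ROI of side `side_um` in every grid cell that fits fully inside the
#' image.  Random grid placement removes selection bias; manual exclusion
#' of out-of-focus regions is modelled by the `kept` flag, which callers
#' may clear per ROI.
#'
#' @param stack an [image_stack()] (supplies pixel size and image shape).
#' @param spacing_um grid pitch in micrometres (>= 1 pixel).
#' @param side_um ROI side in micrometres (default: the spacing);
#'   must not exceed `spacing_um`.
#' @param seed RNG seed for the grid origin.
#' @return A `roi_set`: data.frame with columns `roi_id`, `row0`, `col0`
#'   (0-based top-left corner), `side_px`, `kept`, plus attributes
#'   `spacing_um`, `pixel_size_um`, `image_dim`.  Row/column intervals are
#'   half-open: the ROI covers pixels `row0 .. row0 + side_px - 1`.
#' @examples
#' st <- image_stack(array(runif(512 * 512), c(512, 512, 1)), 0.2, 0.4)
#' nrow(make_roi_grid(st, spacing_um = 20, seed = 1))
#' @export
make_roi_grid <- function(stack, spacing_um, side_um = spacing_um, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size_um
  spacing_px <- as.integer(round(spacing_um / ps))
  side_px <- as.integer(round(side_um / ps))
  if (spacing_px < 1L) stop("grid spacing is smaller than one pixel")
  if (side_px < 1L) stop("ROI side is smaller than one pixel")
  if (side_um > spacing_um) stop("'side_um' must not exceed 'spacing_um'")
  d <- dim(stack$frames)
  if (spacing_px > min(d[1:2]))
    stop("image is smaller than one grid cell")
  set.seed(child_seed(seed, 4L))
  origin <- floor(stats::runif(2, 0, spacing_px))  # (row, col), 0-based
  off <- (spacing_px - side_px) %/% 2L
  # ROI starts on the (infinite) grid that land fully inside the image
  starts_in <- function(o, n) {
    kmin <- ceiling((0 - o - off) / spacing_px)
    kmax <- floor((n - side_px - o - off) / spacing_px)
    if (kmax < kmin) return(integer(0))
    as.integer(o + off + (kmin:kmax) * spacing_px)
  }
  row_starts <- starts_in(origin[1], d[1])
  col_starts <- starts_in(origin[2], d[2])
  if (length(row_starts) == 0L || length(col_starts) == 0L)
    stop("no complete grid cell fits inside the image for this origin")
  grid <- expand.grid(row0 = row_starts, col0 = col_starts)
  rois <- data.frame(roi_id = seq_len(nrow(grid)),
                     row0 = grid$row0, col0 = grid$col0,
                     side_px = side_px, kept = TRUE)
  structure(rois, class = c("roi_set", "data.frame"),
            spacing_um = spacing_um, pixel_size_um = ps,
            image_dim = d[1:2])
}

#' Extract the pixel-by-frame matrix of one ROI
#'
#' @param stack an [image_stack()].
#' @param roi one row of a `roi_set` (or any list with `row0`, `col0`,
#'   `side_px`).
#' @return numeric matrix, `side_px^2` rows (pixels) by `T` columns
#'   (frames).
#' @export
roi_pixels <- function(stack, roi) {
  rows <- (roi$row0 + 1L):(roi$row0 + roi$side_px)
  cols <- (roi$col0 + 1L):(roi$col0 + roi$side_px)
  d <- dim(stack$frames)
  if (max(rows) > d[1] || max(cols) > d[2] || min(rows) < 1L || min(cols) < 1L)
    stop("ROI lies outside the image")
  m <- stack$frames[rows, cols, , drop = FALSE]
  dim(m) <- c(length(rows) * length(cols), d[3])
  m
}

#' Read / write ROI sets as CSV
#'
#' Round-trips the `roi_id`, `row0`, `col0`, `side_px`, `kept` columns
#' losslessly.
#' @param rois a `roi_set`.
#' @param path CSV file path.
#' @return [write_rois()]: `path` invisibly; [read_rois()]: a `roi_set`.
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(as.data.frame(rois)[, c("roi_id", "row0", "col0",
                                           "side_px", "kept")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path)
  structure(df[, c("roi_id", "row0", "col0", "side_px", "kept")],
            class = c("roi_set", "data.frame"))
}

#' Standard time-series preprocessing
#'
#' Applies the canonical order of operations: rolling-ball background
#' subtraction, global linear contrast enhancement, histogram-matching
#' bleach correction.
#'
#' @param stack an [image_stack()].
#' @param radius_px rolling-ball radius (default 50 px).
#' @param reference_frame bleach-correction reference (default 1).
#' @return a preprocessed `image_stack`.
#' @export
preprocess_stack <- function(stack, radius_px = 50L, reference_frame = 1L) {
  correct_bleaching(enhance_contrast(subtract_background(stack, radius_px)),
                    reference_frame)
}
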