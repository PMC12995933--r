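#' Fluorescence image stack
#'
#' Container for a single-channel fluorescence time series: a `H x W x T`
#' array of intensities together with the physical pixel size and frame
#' interval.  All pipeline functions operate on this class.  Intensities
#' are expected (but not forced) to live on the `[0, 1]` scale; the
#' synthetic generator and [enhance_contrast()] produce that scale.
#'
#' @param frames numeric array `H x W x T` (a plain matrix is treated as a
#'   single frame), finite and non-negative.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param frame_interval_s time between consecutive frames in seconds (> 0).
#'
#' @return An object of class `image_stack`: a list with elements `frames`,
#'   `pixel_size_um`, `frame_interval_s`.
#' @examples
#' st <- image_stack(array(runif(16 * 16 * 3), c(16, 16, 3)),
#'                   pixel_size_um = 0.2, frame_interval_s = 0.4)
#' n_frames(st)
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a H x W x T array")
  if (any(!is.finite(frames))) stop("frame intensities must be finite")
  if (min(frames) < 0) stop("frame intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("'frame_interval_s' must be a single positive number")
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
n_frames <- function(x) dim(x$frames)[3L]

#' Extract one frame of a stack as a matrix
#' @param x an `image_stack`.
#' @param t frame index (1-based).
#' @return numeric `H x W` matrix.
#' @export
frame <- function(x, t) {
  stopifnot(inherits(x, "image_stack"), t >= 1, t <= n_frames(x))
  x$frames[, , t]
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "image_stack: %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Read / write image stacks as multi-page grayscale TIFF
#'
#' Time is the page axis.  Pixel size and frame interval are not stored in
#' the TIFF and must be supplied on read.  On write, intensities are
#' clipped to `[0, 1]` (the TIFF grayscale range).
#'
#' @param path TIFF file path.
#' @param pixel_size_um,frame_interval_s physical metadata for the stack.
#' @return [read_image_stack()]: an `image_stack`;
#'   [write_image_stack()]: `path`, invisibly.
#' @export
read_image_stack <- function(path, pixel_size_um, frame_interval_s) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p   # drop extra channels
  })
  frames <- array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  image_stack(frames, pixel_size_um, frame_interval_s)
}

#' @rdname read_image_stack
#' @param stack an `image_stack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)),
                  function(t) clamp01(stack$frames[, , t]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write an integer label mask as 16-bit TIFF
#'
#' Labels are stored as `value / 65535` so that up to 65535 cells
#' round-trip exactly through the 16-bit grayscale TIFF encoding.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
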