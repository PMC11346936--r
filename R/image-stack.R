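#' Time-ordered image stack
#'
#' Container for a grayscale time-lapse recording: a `ny x nx x nt` array of
#' intensities plus the physical metadata needed downstream (pixel size in
#' micrometres per pixel, frame rate in Hz). Intensities are kept as plain
#' numerics; quantization to 16-bit happens only on write.
#'
#' Coordinate convention used throughout the package: image row-major,
#' origin at the top-left pixel, x rightward along columns, y downward along
#' rows, 0-based pixel indices; physical coordinates are pixel index times
#' pixel size.
#'
#' @param frames numeric array `ny x nx x nt` (or a list of matrices).
#' @param pixel_size effective pixel size, micrometres per pixel (> 0).
#' @param frame_rate acquisition rate, Hz (> 0).
#' @param magnification optional objective tag, e.g. `"40x"` or `"60x"`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_rate, magnification = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3) stop("`frames` must be a ny x nx x nt array")
  if (dim(frames)[3] < 2) stop("an image stack needs at least 2 frames")
  stopifnot_positive(pixel_size, frame_rate,
                     .names = c("pixel_size", "frame_rate"))
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate, magnification = magnification),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frames, %.3g um/px, %g Hz%s\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_rate,
              if (is.null(x$magnification)) "" else paste0(", ", x$magnification)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

#' Read a multi-page TIFF into an image stack
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return an `image_stack`.
#' @export
read_image_stack <- function(path, pixel_size, frame_rate, magnification = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  image_stack(simplify2array(pages), pixel_size, frame_rate, magnification)
}

#' Write an image stack as 16-bit multi-page TIFF
#'
#' Intensities are affinely rescaled to the unit range of the whole stack
#' (flat stacks are written as zeros) and stored at 16 bits per sample.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  fr <- stack$frames
  lo <- min(fr); hi <- max(fr)
  fr <- if (hi > lo) (fr - lo) / (hi - lo) else array(0, dim(fr))
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
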