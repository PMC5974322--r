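#' Movie stack: a calibrated T x H x W intensity time series
#'
#' A `movie_stack` bundles a nonnegative intensity array with its physical
#' calibration: the frame rate (`fps`, frames/s) and the pixel size at the
#' sample plane (`um_per_px`, micrometres per pixel). Frames are indexed by
#' the first array dimension; rows (second dimension) run along image y,
#' columns (third) along image x. Pixel centres sit at `(i - 0.5) * um_per_px`
#' for 1-based pixel index `i`; all geometry inside the package is in
#' micrometres.
#'
#' @param data numeric array `T x H x W` of finite, nonnegative intensities
#'   (arbitrary units). A matrix is treated as a single frame.
#' @param fps frame rate in frames per second, `> 0`.
#' @param um_per_px pixel size at the sample in micrometres, `> 0`.
#' @param depth_um optional axial position of the imaged plane in micrometres.
#'
#' @return An object of class `movie_stack`: a list with elements `data`,
#'   `fps`, `um_per_px` and `depth_um`.
#' @examples
#' mov <- movie_stack(array(1, c(4, 8, 8)), fps = 6, um_per_px = 1.05)
#' dim(mov$data)
#' @export
movie_stack <- function(data, fps, um_per_px, depth_um = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a T x H x W array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (any(data < 0)) stop("intensities must be nonnegative", call. = FALSE)
  assert_scalar_pos(fps, "fps")
  assert_scalar_pos(um_per_px, "um_per_px")
  structure(
    list(data = data, fps = fps, um_per_px = um_per_px, depth_um = depth_um),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<movie_stack> %d frame(s) of %d x %d px | %.3g fps | %.4g um/px%s\n",
    d[1], d[2], d[3], x$fps, x$um_per_px,
    if (!is.null(x$depth_um)) sprintf(" | depth %.3g um", x$depth_um) else ""
  ))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Number of frames in a movie stack
#' @param movie a [movie_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[1]

# Time-averaged image (H x W) of a movie stack.
#' @rdname n_frames
#' @export
mean_image <- function(movie) {
  d <- dim(movie$data)
  matrix(colMeans(matrix(movie$data, d[1], d[2] * d[3])), d[2], d[3])
}

# Internal: movie as pixels x time matrix (rows in column-major H x W order).
movie_matrix <- function(movie) {
  d <- dim(movie$data)
  t(matrix(movie$data, d[1], d[2] * d[3]))
}

# Internal: pixels x time matrix back to a movie array.
matrix_to_movie <- function(m, h, w) {
  aperm(array(t(m), c(ncol(m), h, w)), c(1L, 2L, 3L))
}

#' Read a multi-page TIFF time series as a movie stack
#'
#' One TIFF page per frame, 16-bit monochrome. Intensities on disk are
#' 16-bit counts; they are returned as doubles in `[0, 65535]`.
#'
#' @param path path to a multi-page TIFF file.
#' @param um_per_px,fps physical calibration; both are required because TIFF
#'   carries no trustworthy calibration of its own.
#' @param depth_um optional axial position.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, um_per_px, fps, depth_um = NULL) {
  if (missing(um_per_px) || missing(fps)) {
    stop("calibration (`um_per_px`, `fps`) must be supplied", call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = FALSE),
    error = function(e) stop(sprintf("cannot read TIFF '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    stop("mixed page shapes in TIFF: ", paste(unique(shapes), collapse = ", "),
         call. = FALSE)
  }
  h <- dim(pages[[1]])[1]; w <- dim(pages[[1]])[2]
  dat <- array(0, c(length(pages), h, w))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]   # collapse accidental channels
    dat[i, , ] <- round(p * 65535)
  }
  movie_stack(dat, fps = fps, um_per_px = um_per_px, depth_um = depth_um)
}

#' Write a movie stack as a 16-bit multi-page TIFF
#'
#' @param movie a [movie_stack()]; intensities are clamped to `[0, 65535]`
#'   and rounded to integers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[1]), function(t) {
    pmin(pmax(round(movie$data[t, , ]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
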