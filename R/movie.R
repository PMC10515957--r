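#' Movie container
#'
#' A movie is stored as a `d x T` real matrix (`d = height * width` pixels,
#' one column per frame), with pixels unrolled row-major: pixel `(y, x)`
#' (1-based) occupies row `(y-1)*width + x`. All modules in the package use
#' this convention.
#'
#' @param data numeric `d x T` matrix, or a `T x height x width` array.
#' @param height,width field-of-view dimensions in pixels. Inferred when
#'   `data` is a 3D array.
#' @param frame_rate optional acquisition rate in Hz (metadata only).
#' @return an object of class `movie` with elements `data`, `height`,
#'   `width`, `frame_rate`.
#' @examples
#' arr <- array(rnorm(10 * 4 * 5), dim = c(10, 4, 5))
#' m <- movie(arr)
#' dim(m$data)  # 20 x 10
#' @export
movie <- function(data, height = NULL, width = NULL, frame_rate = NULL) {
  if (is.array(data) && length(dim(data)) == 3) {
    dm <- dim(data)
    height <- dm[2]; width <- dm[3]
    d <- height * width
    flat <- matrix(0, d, dm[1])
    for (t in seq_len(dm[1])) flat[, t] <- image_to_unrolled(data[t, , ])
    data <- flat
  }
  if (!is.matrix(data)) stop("`data` must be a d x T matrix or a T x H x W array")
  if (is.null(height) || is.null(width)) stop("height and width are required for matrix input")
  if (height * width != nrow(data)) stop("height * width must equal nrow(data)")
  if (ncol(data) < 2) stop("a movie needs at least 2 frames")
  if (!all(is.finite(data))) stop("movie contains non-finite values")
  structure(
    list(data = data, height = as.integer(height), width = as.integer(width),
         frame_rate = frame_rate),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("<movie> %d x %d px, %d frames%s\n", x$height, x$width,
              ncol(x$data),
              if (is.null(x$frame_rate)) "" else sprintf(" @ %g Hz", x$frame_rate)))
  invisible(x)
}

#' Extract one frame of a movie as an image matrix
#'
#' @param m a [movie].
#' @param t frame index (1-based).
#' @return `height x width` numeric matrix.
#' @export
movie_frame <- function(m, t) {
  stopifnot(inherits(m, "movie"), t >= 1, t <= ncol(m$data))
  unroll_to_image(m$data[, t], m$height, m$width)
}

#' Load a movie from a multi-page TIFF file
#'
#' Frames are read in page order and unrolled row-major into the columns of
#' the movie matrix. Integer TIFFs are read at their native scale
#' (`as.is = TRUE`); float TIFFs as stored.
#'
#' @param path path to a multi-page TIFF stack (one page per frame).
#' @param frame_rate optional frame rate (Hz) to attach as metadata.
#' @param as_is read integer samples at their native scale; the default
#'   (`NULL`) does so for 8/16-bit stacks (typical microscope output) and
#'   reads deeper samples on the `[0, 1]` scale, where R's 32-bit signed
#'   integers would overflow.
#' @return a [movie].
#' @export
load_movie <- function(path, frame_rate = NULL, as_is = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    stop("HDF5 input is not supported by this build; convert to multi-page TIFF")
  }
  if (is.null(as_is)) {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (is.list(info) && !is.null(info$bits.per.sample)) {
      as_is <- info$bits.per.sample <= 16
    } else as_is <- FALSE
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("a movie needs at least 2 frames; got ", length(pages))
  dm <- dim(pages[[1]])
  if (length(dm) != 2) stop("expected single-channel (grayscale) TIFF pages")
  dat <- vapply(pages, image_to_unrolled, numeric(prod(dm)))
  movie(dat, height = dm[1], width = dm[2], frame_rate = frame_rate)
}

#' Write a movie to a multi-page TIFF file
#'
#' Values are affinely rescaled to `[0, 1]` and stored as 32-bit samples;
#' the scale and offset are returned so the transform is invertible.
#'
#' @param m a [movie].
#' @param path output path.
#' @return invisibly, a list with `offset` and `scale` such that
#'   `stored = (value - offset) / scale`; invert with
#'   `load_movie(path, as_is = FALSE)`.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  lo <- min(m$data); hi <- max(m$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(ncol(m$data)), function(t) {
    (unroll_to_image(m$data[, t], m$height, m$width) - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(list(offset = lo, scale = scale))
}

#' Estimate per-pixel noise and normalize a movie to unit noise
#'
#' Estimates the noise scale `sigma` of every pixel trace and divides each
#' trace by its `sigma`, so that downstream stages can assume unit noise per
#' pixel. Two estimators are available:
#'
#' * `"psd_median"` (default): the square root of the median of the
#'   periodogram over the upper half of the frequency range. Slow calcium
#'   signal concentrates at low frequencies, so the high-frequency
#'   periodogram reflects the white-noise floor.
#' * `"diff_mad"`: `mad(diff(trace)) / sqrt(2)`, robust and usable for very
#'   short movies.
#'
#' Movies shorter than 32 frames fall back to `"diff_mad"`.
#'
#' @param m a [movie].
#' @param method `"psd_median"` or `"diff_mad"`.
#' @param epsilon floor for `sigma` (guards zero-variance pixels).
#' @return list with `movie` (normalized) and `noise` (a `noise_model`:
#'   `sigma` vector of length `d`, `method` used).
#' @export
estimate_noise_and_normalize <- function(m, method = c("psd_median", "diff_mad"),
                                         epsilon = 1e-9) {
  stopifnot(inherits(m, "movie"))
  method <- match.arg(method)
  Tn <- ncol(m$data)
  if (method == "psd_median" && Tn < 32) method <- "diff_mad"
  if (method == "psd_median") {
    X <- m$data - rowMeans(m$data)
    # periodogram of each pixel trace: |fft|^2 / T; for white noise with
    # variance s^2 each ordinate has mean s^2
    F <- t(stats::mvfft(t(X)))
    pgram <- (Mod(F)^2) / Tn
    half <- seq.int(floor(Tn / 4) + 1L, floor(Tn / 2) + 1L)
    # periodogram ordinates of white noise are Exp(mean sigma^2); the median
    # of an exponential is sigma^2 * log 2, hence the log(2) correction
    sigma <- sqrt(apply(pgram[, half, drop = FALSE], 1, stats::median) / log(2))
  } else {
    dX <- m$data[, -1, drop = FALSE] - m$data[, -Tn, drop = FALSE]
    sigma <- apply(dX, 1, stats::mad) / sqrt(2)
  }
  nz <- sigma < epsilon
  if (any(nz)) {
    warning(sum(nz), " pixel(s) with ~zero variance; sigma floored at epsilon")
    sigma[nz] <- epsilon
  }
  norm <- m
  norm$data <- m$data / sigma
  list(movie = norm,
       noise = structure(list(sigma = sigma, method = method),
                         class = "noise_model"))
}
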