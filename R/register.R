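# Rigid template registration: every frame is aligned to a global template
# by the peak of the FFT cross-correlation, refined to subpixel precision by
# an upsampled discrete Fourier transform around the integer peak.

# Upsampled DFT of the product spectrum `S` (H x W, complex) evaluated on an
# `nor x noc` grid with spacing 1/usfac, with origin offset (roff, coff) in
# upsampled units. Matrix-multiply form of the zero-padded-FFT upsampling.
dft_upsample <- function(S, nor, noc, usfac, roff, coff) {
  H <- nrow(S); W <- ncol(S)
  fy <- c(0:floor((H - 1) / 2), -(ceiling((H - 1) / 2):1))   # fft frequency order
  fx <- c(0:floor((W - 1) / 2), -(ceiling((W - 1) / 2):1))
  kernr <- exp(2i * pi / (H * usfac) * outer((0:(nor - 1)) - roff, fy))
  kernc <- exp(2i * pi / (W * usfac) * outer(fx, (0:(noc - 1)) - coff))
  kernr %*% S %*% kernc
}

# Estimate the (dy, dx) translation of `img` relative to `template` by
# cross-correlation, to 1/usfac pixel precision.
estimate_shift <- function(img, template, usfac = 10) {
  H <- nrow(img); W <- ncol(img)
  Fi <- stats::fft(img)
  Ft <- stats::fft(template)
  S <- Fi * Conj(Ft)
  cc <- Re(stats::fft(S, inverse = TRUE))
  pk <- which.max(cc)
  py <- ((pk - 1) %% H)
  px <- ((pk - 1) %/% H)
  # wraparound convention: peak at (py, px) means shift py or py - H
  dy <- if (py > H / 2) py - H else py
  dx <- if (px > W / 2) px - W else px
  if (usfac > 1) {
    # refine in a 1.5 px neighborhood at 1/usfac spacing
    n <- ceiling(1.5 * usfac)
    ctr <- floor(n / 2)
    roff <- ctr - dy * usfac
    coff <- ctr - dx * usfac
    ccu <- Re(dft_upsample(S, n, n, usfac, roff, coff))
    pk2 <- which.max(ccu)
    ry <- (pk2 - 1) %% n
    rx <- (pk2 - 1) %/% n
    dy <- (ry - ctr) / usfac + dy
    dx <- (rx - ctr) / usfac + dx
  }
  c(dy = dy, dx = dx)
}

# Translate an image by (-dy, -dx) (i.e. undo an estimated (dy, dx) content
# shift) with bilinear interpolation and edge replication.
apply_shift <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  ys <- (1:H) + dy
  xs <- (1:W) + dx
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y1, x0, drop = FALSE]
  cM <- img[y0, x1, drop = FALSE]; dM <- img[y1, x1, drop = FALSE]
  (1 - wy) * ((a * (1 - rep(wx, each = H))) + cM * rep(wx, each = H)) +
    wy * ((b * (1 - rep(wx, each = H))) + dM * rep(wx, each = H))
}

#' Rigidly register a movie to a global template
#'
#' Aligns every frame to a template by whole-frame translation. The template
#' is initialized as the mean frame and refined by `n_template_iters` rounds
#' of (register all frames to the template; recompute the template as the
#' mean of the registered frames). Per-frame shifts are the argmax of the
#' FFT cross-correlation with subpixel refinement by an upsampled
#' correlation peak; frames are shifted back with bilinear interpolation and
#' edge replication. Shifts larger than `max_shift` are clipped to the bound
#' and flagged.
#'
#' @param m a [movie].
#' @param max_shift maximum allowed |shift| per axis, in pixels; must be
#'   below `min(height, width) / 4`.
#' @param n_template_iters template refinement rounds (default 3).
#' @param upsample subpixel upsampling factor (default 10, i.e. 0.1 px).
#' @return a `registration_result`: list with `shifts` (`T x 2` matrix of
#'   `(dy, dx)`), `template` (`height x width`), `registered` ([movie]),
#'   and `clipped` (logical, per frame).
#' @export
rigid_register <- function(m, max_shift = 8, n_template_iters = 3, upsample = 10) {
  stopifnot(inherits(m, "movie"))
  if (max_shift >= min(m$height, m$width) / 4) {
    stop("max_shift must be < min(height, width) / 4")
  }
  Tn <- ncol(m$data)
  frames <- lapply(seq_len(Tn), function(t) movie_frame(m, t))
  template <- Reduce(`+`, frames) / Tn
  if (all(template == 0)) stop("degenerate all-zero template")
  shifts <- matrix(0, Tn, 2, dimnames = list(NULL, c("dy", "dx")))
  clipped <- logical(Tn)
  registered <- frames
  for (iter in seq_len(max(1L, n_template_iters))) {
    for (t in seq_len(Tn)) {
      s <- estimate_shift(frames[[t]], template, usfac = upsample)
      cl <- abs(s) > max_shift
      s <- pmin(pmax(s, -max_shift), max_shift)
      shifts[t, ] <- s
      clipped[t] <- any(cl)
      registered[[t]] <- apply_shift(frames[[t]], s[1], s[2])
    }
    template <- Reduce(`+`, registered) / Tn
  }
  reg <- m
  reg$data <- vapply(registered, image_to_unrolled, numeric(m$height * m$width))
  structure(
    list(shifts = shifts, template = template, registered = reg,
         clipped = clipped),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> %d frames, max |shift| = %.2f px, %d clipped\n",
              nrow(x$shifts), max(abs(x$shifts)), sum(x$clipped)))
  invisible(x)
}
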