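# Patchwise adaptive-rank SVD compression ("PMD-lite"): overlapping spatial
# patches are individually decomposed by a truncated randomized SVD, ranks
# are chosen against the noise edge for unit-variance entries, and the
# patches are stitched with a bilinear partition-of-unity taper so that the
# sparse spatial basis U has single-patch column support.

#' Build an overlapping patch layout for a field of view
#'
#' Patches of `patch_height x patch_width` pixels are placed on a grid with
#' stride `patch * (1 - overlap)` in each dimension; the last patch in each
#' dimension is shifted to touch the border, so the patches cover every
#' pixel. Each patch carries a bilinear (triangular) taper weight image;
#' after per-pixel renormalization the weights of the patches covering any
#' pixel sum to exactly 1.
#'
#' @param height,width FOV size in pixels.
#' @param patch_height,patch_width patch size in pixels (clipped to FOV).
#' @param overlap fraction of overlap between neighboring patches in each
#'   dimension, in `(0, 1)`; default 0.5.
#' @return a `patch_layout`: list with per-patch row-major pixel index
#'   vectors (`pixels`), per-patch weight vectors (`weights`, aligned with
#'   `pixels`), patch bounding boxes, and the FOV geometry.
#' @export
patch_layout <- function(height, width, patch_height = 32, patch_width = 32,
                         overlap = 0.5) {
  stopifnot(overlap > 0, overlap < 1)
  patch_height <- min(patch_height, height)
  patch_width <- min(patch_width, width)
  starts <- function(n, p) {
    stride <- max(1L, round(p * (1 - overlap)))
    s <- seq.int(1L, max(1L, n - p + 1L), by = stride)
    if (s[length(s)] + p - 1L < n) s <- c(s, n - p + 1L)
    unique(s)
  }
  ys <- starts(height, patch_height)
  xs <- starts(width, patch_width)
  taper <- function(p) {
    # triangular taper, strictly positive so coverage is never lost
    w <- pmin(seq_len(p), p + 1 - seq_len(p))
    w / max(w)
  }
  ty <- taper(patch_height); tx <- taper(patch_width)
  patches <- list()
  wsum <- numeric(height * width)
  for (y0 in ys) for (x0 in xs) {
    yy <- y0:(y0 + patch_height - 1L)
    xx <- x0:(x0 + patch_width - 1L)
    # row-major indices of the patch pixels (x fastest)
    pix <- as.integer(outer(xx, (yy - 1L) * width, `+`))
    w <- as.numeric(outer(tx, ty))      # aligned with pix (x fastest)
    patches[[length(patches) + 1L]] <-
      list(pixels = pix, weights = w, y0 = y0, x0 = x0)
    wsum[pix] <- wsum[pix] + w
  }
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    patches[[i]]$weights <- p$weights / wsum[p$pixels]
  }
  structure(
    list(patches = patches, height = as.integer(height),
         width = as.integer(width),
         patch_height = as.integer(patch_height),
         patch_width = as.integer(patch_width), overlap = overlap),
    class = "patch_layout"
  )
}

# Randomized truncated SVD of X (p x T): range finding with `oversample`
# extra directions and `power_iters` power iterations; deterministic given
# the local RNG seed.
randomized_svd <- function(X, rank, oversample = 10, power_iters = 2) {
  p <- nrow(X); Tn <- ncol(X)
  l <- min(rank + oversample, p, Tn)
  Om <- matrix(stats::rnorm(Tn * l), Tn, l)
  Q <- qr.Q(qr(X %*% Om))
  for (i in seq_len(power_iters)) {
    Q <- qr.Q(qr(crossprod(X, Q)))
    Q <- qr.Q(qr(X %*% Q))
  }
  B <- crossprod(Q, X)                  # l x T
  sv <- svd(B)
  k <- min(rank, length(sv$d))
  list(u = (Q %*% sv$u)[, seq_len(k), drop = FALSE],
       d = sv$d[seq_len(k)],
       v = sv$v[, seq_len(k), drop = FALSE])
}

#' Compress and denoise a movie into a sparse spatial basis
#'
#' Decomposes a noise-normalized movie into `Y ~ U V + means` where each
#' column of the sparse `d x K` matrix `U` is supported on a single spatial
#' patch and `V` is `K x T`. Per patch (p pixels x T frames), the per-pixel
#' temporal mean is removed and a truncated SVD is computed; components are
#' retained while their singular value exceeds the noise edge
#' `(sqrt(p) + sqrt(T)) * (1 + rank_margin)` expected for unit-variance
#' i.i.d. noise (valid because the input is noise-normalized). Retained
#' spatial vectors are multiplied by the patch's partition-of-unity taper
#' weights and concatenated into `U`; singular values are folded into `V`.
#'
#' @param m a noise-normalized [movie].
#' @param patch_height,patch_width,overlap patch layout parameters
#'   (see [patch_layout]).
#' @param rank_margin relative margin on the noise edge (default 0.05).
#' @param max_rank cap on retained rank per patch (default 50).
#' @param seed RNG seed for the randomized SVD range finder (default 0);
#'   the caller's RNG state is untouched.
#' @return a `pmd` object: `U` (sparse `dgCMatrix` `d x K`), `V` (`K x T`),
#'   `means` (length-`d` per-pixel means), `layout`, `K`, and the FOV
#'   geometry (`height`, `width`).
#' @export
decompose_pmd <- function(m, patch_height = 32, patch_width = 32,
                          overlap = 0.5, rank_margin = 0.05, max_rank = 50,
                          seed = 0) {
  stopifnot(inherits(m, "movie"))
  layout <- patch_layout(m$height, m$width, patch_height, patch_width, overlap)
  Tn <- ncol(m$data)
  means <- rowMeans(m$data)
  ui <- list(); uj <- list(); ux <- list(); Vs <- list()
  K <- 0L
  patch_of <- integer(0)
  with_local_seed(seed, {
    for (pi in seq_along(layout$patches)) {
      p <- layout$patches[[pi]]
      X <- m$data[p$pixels, , drop = FALSE] - means[p$pixels]
      np <- length(p$pixels)
      edge <- (sqrt(np) + sqrt(Tn)) * (1 + rank_margin)
      sv <- randomized_svd(X, rank = min(max_rank, np, Tn))
      keep <- which(sv$d > edge)
      if (length(keep) == 0) next
      for (k in keep) {
        K <- K + 1L
        ui[[K]] <- p$pixels
        uj[[K]] <- rep.int(K, np)
        ux[[K]] <- sv$u[, k] * p$weights
        Vs[[K]] <- sv$d[k] * sv$v[, k]
        patch_of[K] <- pi
      }
    }
  })
  d <- m$height * m$width
  if (K == 0) {
    warning("no components exceeded the noise edge in any patch; K = 0")
    U <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(d, 0))
    V <- matrix(0, 0, Tn)
  } else {
    U <- Matrix::sparseMatrix(i = unlist(ui), j = unlist(uj), x = unlist(ux),
                              dims = c(d, K))
    V <- do.call(rbind, lapply(Vs, as.numeric))
  }
  structure(
    list(U = U, V = V, means = means, layout = layout, K = K,
         patch_of = patch_of, height = m$height, width = m$width),
    class = "pmd"
  )
}

#' @export
print.pmd <- function(x, ...) {
  cat(sprintf("<pmd> %d x %d px, K = %d (%d patches), T = %d\n",
              x$height, x$width, x$K, length(x$layout$patches), ncol(x$V)))
  invisible(x)
}

#' Reconstruct denoised frames from a compressed movie
#'
#' Returns `U V[, t] + means` for the requested frames, reshaped to images.
#'
#' @param pmd a [decompose_pmd] result.
#' @param frames integer frame indices (1-based).
#' @param add_means re-add the stored per-pixel temporal means
#'   (default TRUE).
#' @return array `length(frames) x height x width`.
#' @export
reconstruct_frames <- function(pmd, frames, add_means = TRUE) {
  stopifnot(inherits(pmd, "pmd"))
  Tn <- ncol(pmd$V)
  if (any(frames < 1 | frames > Tn)) stop("frame index out of range [1, ", Tn, "]")
  X <- if (pmd$K > 0) {
    as.matrix(pmd$U %*% pmd$V[, frames, drop = FALSE])
  } else {
    matrix(0, pmd$height * pmd$width, length(frames))
  }
  if (add_means) X <- X + pmd$means
  out <- array(0, dim = c(length(frames), pmd$height, pmd$width))
  for (i in seq_along(frames)) {
    out[i, , ] <- unroll_to_image(X[, i], pmd$height, pmd$width)
  }
  out
}
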