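# Temporal sparsening: AR(1) deconvolution of the denoised movie (an
# active-set solver per pixel, or a fast naive operator acting directly on
# the temporal basis V), followed by re-denoising via projection onto the
# sparse spatial basis U. The sparsened movie is kept factorized as U P.

#' Estimate the AR(1) decay coefficient from a compressed movie
#'
#' Computes `g` as the median, over the `n_pixels` highest-energy pixel
#' traces of the denoised movie, of the ratio (lag-2 autocovariance) /
#' (lag-1 autocovariance), clipped to `[0, 0.999]`. For a calcium transient
#' driven AR(1) process both autocovariances decay by `g` per lag, so the
#' ratio is robust to the (white) noise that only inflates lag 0.
#'
#' @param pmd a [decompose_pmd] result with `K >= 1`.
#' @param n_pixels number of top-energy pixels to pool (default 100).
#' @return scalar `g` in `[0, 0.999]`.
#' @export
estimate_ar_coefficient <- function(pmd, n_pixels = 100) {
  stopifnot(inherits(pmd, "pmd"))
  if (pmd$K < 1) stop("cannot estimate g from an empty (K = 0) decomposition")
  VVt <- tcrossprod(pmd$V)
  energy <- Matrix::rowSums((pmd$U %*% VVt) * pmd$U)
  idx <- order(energy, decreasing = TRUE)[seq_len(min(n_pixels, length(energy)))]
  X <- as.matrix(pmd$U[idx, , drop = FALSE] %*% pmd$V)
  X <- X - rowMeans(X)
  Tn <- ncol(X)
  ac1 <- rowSums(X[, -1, drop = FALSE] * X[, -Tn, drop = FALSE])
  ac2 <- rowSums(X[, -(1:2), drop = FALSE] * X[, -((Tn - 1):Tn), drop = FALSE])
  if (!all(is.finite(ac1)) || !all(is.finite(ac2))) {
    stop("non-finite autocovariances in AR coefficient estimation")
  }
  r <- ac2[ac1 != 0] / ac1[ac1 != 0]
  if (length(r) == 0) return(0)
  min(max(stats::median(r), 0), 0.999)
}

#' AR(1) model parameters for deconvolution
#'
#' @param g AR(1) decay coefficient in `[0, 1)`.
#' @param lam nonnegative sparsity weight on the deconvolved activity.
#' @param baseline_percentile percentile of the trace subtracted as a
#'   constant baseline before deconvolution, in `[0, 100]`.
#' @return an `ar_model` list.
#' @export
ar_model <- function(g, lam = 1.0, baseline_percentile = 20) {
  stopifnot(g >= 0, g < 1, lam >= 0,
            baseline_percentile >= 0, baseline_percentile <= 100)
  structure(list(g = g, lam = lam,
                 baseline_percentile = baseline_percentile),
            class = "ar_model")
}

#' Sparse nonnegative AR(1) deconvolution of a single trace
#'
#' Solves, by a pool-adjacent-violators active-set sweep, the problem
#' `min_c 1/2 ||c - (y - b)||^2 + lam * sum(s)` subject to
#' `s_t = c_t - g c_{t-1} >= 0` (with `s_1 = c_1 >= 0`), where `b` is the
#' `baseline_percentile` percentile of `y`. The L1 penalty is folded into
#' the target (`y_t - lam * (1 - g)` for `t < T`, `y_T - lam`), after which
#' pools of frames sharing one free value, decaying geometrically at rate
#' `g`, are merged left-to-right until the constraint holds; negative pool
#' values are clamped at zero.
#'
#' @param trace numeric T-vector (finite).
#' @param ar an [ar_model].
#' @return list with `c` (denoised calcium, in baseline-subtracted units)
#'   and `s` (deconvolved activity, `s >= 0`).
#' @export
deconvolve_oasis <- function(trace, ar) {
  stopifnot(inherits(ar, "ar_model"), all(is.finite(trace)))
  Tn <- length(trace)
  g <- ar$g
  b <- stats::quantile(trace, ar$baseline_percentile / 100, names = FALSE)
  y <- trace - b
  mu <- rep(1 - g, Tn); mu[Tn] <- 1
  y <- y - ar$lam * mu
  # pools: value v = h/w, h = sum g^j y, w = sum g^{2j}, length l, start t
  h <- numeric(Tn); w <- numeric(Tn); l <- integer(Tn); st <- integer(Tn)
  np <- 0L
  for (t in seq_len(Tn)) {
    np <- np + 1L
    h[np] <- y[t]; w[np] <- 1; l[np] <- 1L; st[np] <- t
    while (np >= 2L && h[np] / w[np] < g^l[np - 1L] * (h[np - 1L] / w[np - 1L])) {
      gl <- g^l[np - 1L]
      h[np - 1L] <- h[np - 1L] + gl * h[np]
      w[np - 1L] <- w[np - 1L] + gl^2 * w[np]
      l[np - 1L] <- l[np - 1L] + l[np]
      np <- np - 1L
    }
  }
  cvec <- numeric(Tn)
  for (i in seq_len(np)) {
    v <- max(h[i] / w[i], 0)
    cvec[st[i]:(st[i] + l[i] - 1L)] <- v * g^(0:(l[i] - 1L))
  }
  s <- c(cvec[1], cvec[-1] - g * cvec[-Tn])
  s[s < 0 & s > -1e-12] <- 0    # numerical dust inside pools
  list(c = cvec, s = s)
}

#' Naive AR(1) deconvolution on the temporal basis
#'
#' Applies the backshift-differencing operator `s_t = c_t - g c_{t-1}`
#' directly to the rows of `V`, which by linearity equals per-pixel naive
#' deconvolution of the dense denoised movie `U V`. The first frame is kept
#' as-is. Negative values are retained in the coefficients; frames are
#' rectified at zero only when rendered for detection.
#'
#' @param pmd a [decompose_pmd] result.
#' @param g AR(1) coefficient in `[0, 1)`.
#' @return a `sparse_movie`: list with coefficients `P` (`K x T`) and the
#'   backing `pmd`; the sparsened movie `U P` is only ever materialized
#'   frame-by-frame.
#' @export
deconvolve_naive_on_V <- function(pmd, g) {
  stopifnot(inherits(pmd, "pmd"), g >= 0, g < 1)
  V <- pmd$V
  Tn <- ncol(V)
  P <- V
  if (Tn >= 2) P[, 2:Tn] <- V[, 2:Tn, drop = FALSE] - g * V[, 1:(Tn - 1), drop = FALSE]
  structure(list(P = P, pmd = pmd), class = "sparse_movie")
}

#' @export
print.sparse_movie <- function(x, ...) {
  cat(sprintf("<sparse_movie> K = %d, T = %d (factorized U P)\n",
              nrow(x$P), ncol(x$P)))
  invisible(x)
}

#' Project a pixel-space movie onto the spatial basis
#'
#' Computes `P = (U'U)^{-1} U' Z` so that `U P` is the least-squares
#' projection of `Z` onto the column space of `U`; the residual `Z - U P`
#' is orthogonal to that column space. If `U'U` is ill-conditioned a ridge
#' of `1e-8 I` is added. Projecting an already-projected movie is the
#' identity on `P`.
#'
#' @param pmd a [decompose_pmd] result with `K >= 1`.
#' @param Z a dense `d x n` matrix of pixel-space frames, or a
#'   `sparse_movie` (in which case its coefficients are returned unchanged,
#'   since `U P` already lies in the subspace).
#' @return a `sparse_movie`.
#' @export
project_onto_spatial_basis <- function(pmd, Z) {
  stopifnot(inherits(pmd, "pmd"))
  if (pmd$K < 1) stop("cannot project onto an empty (K = 0) basis")
  if (inherits(Z, "sparse_movie")) {
    stopifnot(identical(dim(Z$pmd$U), dim(pmd$U)))
    return(structure(list(P = Z$P, pmd = pmd), class = "sparse_movie"))
  }
  P <- solve_gram(pmd$U, as.matrix(Matrix::crossprod(pmd$U, Z)))
  structure(list(P = P, pmd = pmd), class = "sparse_movie")
}

# Solve (U'U) X = B with a ridge fallback for ill-conditioned Gram matrices.
solve_gram <- function(U, B) {
  G <- as.matrix(Matrix::crossprod(U))
  out <- tryCatch(solve(G, B), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    out <- solve(G + 1e-8 * diag(nrow(G)), B)
  }
  out
}

#' Sparsen a compressed movie
#'
#' High-level sparsening entry point. The default `"naive"` path applies
#' [deconvolve_naive_on_V] on the temporal basis (O(KT)); the `"oasis"`
#' path runs [deconvolve_oasis] on every pixel trace of the denoised movie
#' (streamed in pixel blocks, never materializing the full movie) and
#' projects the result back onto `U` via [project_onto_spatial_basis].
#'
#' @param pmd a [decompose_pmd] result.
#' @param method `"naive"` or `"oasis"`.
#' @param g AR(1) coefficient; `NULL` (default) estimates it with
#'   [estimate_ar_coefficient].
#' @param lam sparsity weight for the OASIS path.
#' @param baseline_percentile baseline percentile for the OASIS path.
#' @param block_pixels pixel block size for the streamed OASIS path.
#' @return a `sparse_movie`.
#' @export
sparsen_movie <- function(pmd, method = c("naive", "oasis"), g = NULL,
                          lam = 1.0, baseline_percentile = 20,
                          block_pixels = 1024) {
  stopifnot(inherits(pmd, "pmd"))
  method <- match.arg(method)
  if (pmd$K < 1) return(structure(list(P = pmd$V, pmd = pmd), class = "sparse_movie"))
  if (is.null(g)) g <- estimate_ar_coefficient(pmd)
  if (method == "naive") return(deconvolve_naive_on_V(pmd, g))
  ar <- ar_model(g = g, lam = lam, baseline_percentile = baseline_percentile)
  d <- nrow(pmd$U); Tn <- ncol(pmd$V)
  UtZ <- matrix(0, pmd$K, Tn)
  for (start in seq(1, d, by = block_pixels)) {
    idx <- start:min(start + block_pixels - 1, d)
    Ub <- pmd$U[idx, , drop = FALSE]
    Zb <- as.matrix(Ub %*% pmd$V)
    for (i in seq_along(idx)) {
      Zb[i, ] <- deconvolve_oasis(Zb[i, ], ar)$s
    }
    UtZ <- UtZ + as.matrix(Matrix::crossprod(Ub, Zb))
  }
  structure(list(P = solve_gram(pmd$U, UtZ), pmd = pmd), class = "sparse_movie")
}

# Render rectified sparsened frames for a pixel subset: pmax(U[pix,] P[,t], 0).
render_sparse_frames <- function(sparse, pixels, frames) {
  X <- as.matrix(sparse$pmd$U[pixels, , drop = FALSE] %*%
                   sparse$P[, frames, drop = FALSE])
  X[X < 0] <- 0
  X
}
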