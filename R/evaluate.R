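# Recovery evaluation: greedy matching of estimates to ground truth by
# spatial then temporal cosine similarity, recovery accuracy / false
# positive count, the oracle baseline (true footprints, traces by
# nonnegative regression), and demixing-video export.

#' Match estimated components to ground truth
#'
#' Ground-truth neurons are processed in descending brightness
#' (`max(a_i) * max(c_i)`). For each, the candidate set is the estimates
#' whose footprint cosine similarity is at least `spatial_threshold`; the
#' winner is the not-yet-matched candidate with the highest temporal cosine
#' similarity (ties broken by lowest estimate index). A truth neuron with
#' no available candidate is unmatched with similarity 0.
#'
#' @param truth_A,truth_C ground-truth footprints (`d x N`) and traces
#'   (`N x T`).
#' @param est_A,est_C estimated footprints and traces.
#' @param spatial_threshold footprint cosine threshold for candidacy
#'   (default 0.5).
#' @return a `match_result`: `pairs` (data.frame truth, estimate,
#'   similarity), `unmatched_truth`, `unmatched_estimates`,
#'   `spatial_threshold`.
#' @export
match_to_ground_truth <- function(truth_A, truth_C, est_A, est_C,
                                  spatial_threshold = 0.5) {
  truth_A <- as.matrix(truth_A); est_A <- as.matrix(est_A)
  truth_C <- as.matrix(truth_C); est_C <- as.matrix(est_C)
  Nt <- ncol(truth_A); Ne <- ncol(est_A)
  if (Nt == 0) stop("empty ground truth")
  bright <- apply(truth_A, 2, max) * apply(truth_C, 1, max)
  ordert <- order(bright, decreasing = TRUE)
  taken <- logical(Ne)
  rows <- list()
  unmatched_truth <- integer(0)
  spat <- if (Ne > 0) {
    nt <- sqrt(colSums(truth_A^2)); ne <- sqrt(colSums(est_A^2))
    ne[ne == 0] <- Inf
    sw <- crossprod(truth_A, est_A) / outer(pmax(nt, 1e-300), ne)
    sw
  } else matrix(0, Nt, 0)
  for (i in ordert) {
    cand <- which(spat[i, ] >= spatial_threshold & !taken)
    if (length(cand) == 0) {
      unmatched_truth <- c(unmatched_truth, i)
      next
    }
    tsim <- vapply(cand, function(j) cosine_sim(truth_C[i, ], est_C[j, ]),
                   numeric(1))
    j <- cand[which.max(tsim)]      # which.max takes the first = lowest index
    taken[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(truth = i, estimate = j,
                                            similarity = max(tsim))
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(truth = integer(0), estimate = integer(0),
               similarity = numeric(0))
  structure(list(pairs = pairs,
                 unmatched_truth = sort(unmatched_truth),
                 unmatched_estimates = which(!taken),
                 spatial_threshold = spatial_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), %d unmatched truth, %d unmatched estimate(s)\n",
              nrow(x$pairs), length(x$unmatched_truth),
              length(x$unmatched_estimates)))
  invisible(x)
}

#' Score a match: recovery accuracy and false positive count
#'
#' Recovery accuracy is the mean temporal similarity over all ground-truth
#' neurons (unmatched truths contribute 0); the false positive count (FPC)
#' is the number of estimates left unmatched.
#'
#' @param match a [match_to_ground_truth] result.
#' @param n_truth number of ground-truth neurons.
#' @return list with `recovery_accuracy` and `fpc`.
#' @export
score_recovery <- function(match, n_truth) {
  stopifnot(inherits(match, "match_result"), n_truth > 0)
  list(recovery_accuracy = sum(match$pairs$similarity) / n_truth,
       fpc = length(match$unmatched_estimates))
}

#' Oracle demixing: true footprints, traces by nonnegative regression
#'
#' Given the true spatial footprints, estimates only the temporal traces by
#' `min_{C >= 0} ||Y - A C||_F^2`, solved by HALS coordinate sweeps until
#' the relative objective change falls below `tol`.
#'
#' @param Y dense `d x T` movie matrix (or a [movie]).
#' @param A_true `d x N` footprints.
#' @param tol relative objective convergence tolerance (default 1e-8).
#' @param max_sweeps sweep cap (default 200).
#' @return `N x T` nonnegative trace matrix.
#' @export
oracle_demix <- function(Y, A_true, tol = 1e-8, max_sweeps = 200) {
  if (inherits(Y, "movie")) Y <- Y$data
  A <- as.matrix(A_true)
  if (ncol(A) == 0) stop("empty A_true")
  AtY <- crossprod(A, Y)
  AtA <- crossprod(A)
  C <- matrix(0, ncol(A), ncol(Y))
  obj_const <- sum(Y^2)
  obj <- function(C) {
    obj_const - 2 * sum(AtY * C) + sum((AtA %*% C) * C)
  }
  last <- obj(C)
  for (s in seq_len(max_sweeps)) {
    for (i in seq_len(ncol(A))) {
      if (AtA[i, i] <= 0) next
      r <- AtY[i, ] - as.numeric(AtA[i, , drop = FALSE] %*% C)
      C[i, ] <- pmax(0, C[i, ] + r / AtA[i, i])
    }
    cur <- obj(C)
    if (last - cur <= tol * max(abs(last), 1)) break
    last <- cur
  }
  C
}

# Map component index to a distinct RGB hue.
component_colors <- function(n) {
  if (n == 0) return(matrix(0, 0, 3))
  h <- ((seq_len(n) - 1) * 0.6180339887) %% 1   # golden-ratio hue spacing
  t(vapply(h, function(hh) as.numeric(grDevices::col2rgb(grDevices::hsv(hh, 0.9, 1)) / 255),
           numeric(3)))
}

#' Export a tiled-panel demixing video
#'
#' Writes a multi-page TIFF in which every frame tiles the diagnostic
#' panels side by side: raw data (when a raw movie is supplied), denoised
#' data, summed signal estimates `A C`, estimates colored (each component
#' in a distinct hue), ground truth colored (when truth is supplied),
#' static background, fluctuating background, and the mean-subtracted
#' residual (denoised - signal - background).
#'
#' @param pmd a [decompose_pmd] result.
#' @param result a [run_localnmf] result.
#' @param path output TIFF path.
#' @param truth optional `ground_truth` (adds the ground-truth panel).
#' @param raw optional raw [movie] (adds the raw panel).
#' @param frames frame indices to export (default: first
#'   `min(T, 100)`).
#' @return invisibly, the panel names in tile order.
#' @export
export_demix_video <- function(pmd, result, path, truth = NULL, raw = NULL,
                               frames = NULL) {
  stopifnot(inherits(pmd, "pmd"), inherits(result, "demix_result"))
  Tn <- ncol(pmd$V)
  if (is.null(frames)) frames <- seq_len(min(Tn, 100))
  H <- pmd$height; W <- pmd$width; d <- H * W
  A <- result$neurons$A; C <- result$neurons$C
  bg <- result$background
  n <- ncol(A)
  cols <- component_colors(n)
  tcols <- if (!is.null(truth)) component_colors(ncol(truth$A)) else NULL
  panels <- c(if (!is.null(raw)) "Raw Data",
              "Denoised Data", "Signal Estimates", "Estimates Colored",
              if (!is.null(truth)) "Ground Truth",
              "Static Background", "Fluctuating Background",
              "Mean Sub Residual")
  np <- length(panels)
  nc <- ceiling(np / 2)
  denoised_all <- if (pmd$K > 0) pmd$U %*% pmd$V[, frames, drop = FALSE] else
    Matrix::Matrix(0, d, length(frames))
  denoised_all <- as.matrix(denoised_all) + pmd$means
  sig_all <- if (n > 0) A %*% C[, frames, drop = FALSE] else matrix(0, d, length(frames))
  bf_all <- if (pmd$K > 0) as.matrix(pmd$U %*% bg$Q[, frames, drop = FALSE]) else
    matrix(0, d, length(frames))
  scale_ref <- max(denoised_all, 1e-12)
  to_img <- function(v) unroll_to_image(pmin(pmax(v / scale_ref, 0), 1), H, W)
  color_img <- function(Amat, ct, colmat) {
    out <- array(0, dim = c(H, W, 3))
    if (length(ct) == 0) return(out)
    for (i in seq_along(ct)) {
      img <- unroll_to_image(Amat[, i] * ct[i] / scale_ref, H, W)
      for (ch in 1:3) out[, , ch] <- out[, , ch] + colmat[i, ch] * img
    }
    pmin(pmax(out, 0), 1)
  }
  pages <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    imgs <- list()
    if (!is.null(raw)) {
      imgs[["Raw Data"]] <- to_img(raw$data[, t])
    }
    imgs[["Denoised Data"]] <- to_img(denoised_all[, fi])
    imgs[["Signal Estimates"]] <- to_img(sig_all[, fi])
    imgs[["Estimates Colored"]] <- color_img(A, if (n > 0) C[, t] else numeric(0), cols)
    if (!is.null(truth)) {
      imgs[["Ground Truth"]] <- color_img(as.matrix(truth$A), truth$C[, t], tcols)
    }
    imgs[["Static Background"]] <- to_img(bg$b)
    imgs[["Fluctuating Background"]] <- to_img(bf_all[, fi])
    resid <- denoised_all[, fi] - sig_all[, fi] - bg$b - bf_all[, fi]
    resid <- resid - mean(resid)
    imgs[["Mean Sub Residual"]] <-
      unroll_to_image(pmin(pmax(resid / scale_ref + 0.5, 0), 1), H, W)
    tile <- array(0, dim = c(2 * H, nc * W, 3))
    for (pi in seq_along(panels)) {
      r0 <- if (pi <= nc) 0 else H
      c0 <- ((pi - 1) %% nc) * W
      img <- imgs[[panels[pi]]]
      if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(H, W, 3))
      tile[r0 + 1:H, c0 + 1:W, ] <- img
    }
    pages[[fi]] <- tile
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(panels)
}
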