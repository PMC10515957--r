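# Footprint detection on the sparsened movie: frames are ranked by
# brightness per spatial patch, a pluggable detector proposes candidate
# masks on the brightest frames, and candidates are filtered into a
# distinct, high-confidence initialization A_init by confidence and cosine
# de-duplication rules.

#' Detection filtering parameters
#'
#' Thresholds governing which detector proposals are accepted into the
#' footprint initialization.
#'
#' @param cmin minimum detector confidence (default 0.7).
#' @param treal maximum weighted-footprint cosine similarity against
#'   already-accepted components (default 0.65, midpoint of the working
#'   range 0.5-0.8).
#' @param tbin maximum binary-support cosine similarity against accepted
#'   components (default 0.65).
#' @param n number of brightest frames examined per patch (default 100;
#'   working range 50-150).
#' @param patch_size detection patch side in pixels (default 20).
#' @param patch_pad padding, in pixels, around each patch when rendering
#'   frames so border cells are seen whole (default 8, about half a soma
#'   diameter).
#' @param max_frame_overlap maximum mask cosine against other detections in
#'   the same frame (default 0.2).
#' @return a `detection_params` list.
#' @export
detection_params <- function(cmin = 0.7, treal = 0.65, tbin = 0.65, n = 100,
                             patch_size = 20, patch_pad = 8,
                             max_frame_overlap = 0.2) {
  for (v in c(cmin, treal, tbin, max_frame_overlap)) {
    stopifnot(v >= 0, v <= 1)
  }
  stopifnot(n >= 1, patch_size >= 1, patch_pad >= 0)
  structure(list(cmin = cmin, treal = treal, tbin = tbin, n = as.integer(n),
                 patch_size = as.integer(patch_size),
                 patch_pad = as.integer(patch_pad),
                 max_frame_overlap = max_frame_overlap),
            class = "detection_params")
}

#' Rank frames of a sparsened movie by patch brightness
#'
#' Frames are ordered by descending maximum of the rectified sparsened
#' movie `max(0, U P)` over the given patch pixels, computed from the
#' factors without materializing the full movie. Ties break by ascending
#' frame index (stable sort), so the order is deterministic.
#'
#' @param sparse a `sparse_movie`.
#' @param pixels row-major pixel indices of the patch.
#' @return integer vector of frame indices (1-based), brightest first.
#' @export
rank_frames_by_brightness <- function(sparse, pixels) {
  stopifnot(inherits(sparse, "sparse_movie"), length(pixels) > 0)
  X <- as.matrix(sparse$pmd$U[pixels, , drop = FALSE] %*% sparse$P)
  bright <- apply(X, 2, function(col) max(col, 0))
  order(bright, decreasing = TRUE)
}

#' Baseline blob detector
#'
#' A deterministic detector usable without trained weights: the frame is
#' thresholded at `rel_thresh` times its maximum, 8-connected components
#' with pixel count in `[min_px, max_px]` become candidate masks, and each
#' candidate's confidence is its peak value divided by the frame maximum.
#'
#' @param frame nonnegative image matrix.
#' @param min_px,max_px admissible component sizes in pixels.
#' @param rel_thresh relative threshold in `(0, 1)` (default 0.3).
#' @return list of candidates, each a list with `mask` (logical matrix) and
#'   `confidence`; empty list when nothing is found.
#' @export
baseline_blob_detector <- function(frame, min_px = 30, max_px = 500,
                                   rel_thresh = 0.3) {
  fmax <- max(frame)
  if (fmax <= 0) return(list())
  lab <- label_components_8(frame >= rel_thresh * fmax)
  out <- list()
  for (k in seq_len(max(lab))) {
    mask <- lab == k
    npx <- sum(mask)
    if (npx < min_px || npx > max_px) next
    out[[length(out) + 1L]] <- list(mask = mask,
                                    confidence = max(frame[mask]) / fmax)
  }
  out
}

#' Wrap a detector function into the detector interface
#'
#' A detector is any function mapping a nonnegative image to a list of
#' `(mask, confidence)` candidates. This wrapper attaches a name so
#' provenance records stay readable.
#'
#' @param fn function(frame image) -> list of list(mask, confidence).
#' @param name short identifier.
#' @return a `detector` object.
#' @export
detector <- function(fn, name = "custom") {
  stopifnot(is.function(fn))
  structure(list(detect = fn, name = name), class = "detector")
}

#' The default blob detector wrapped as a `detector`
#'
#' Runs [baseline_blob_detector] and additionally discards non-compact
#' masks: components whose pixel count is below `min_fill` times the area
#' of the bounding-box ellipse (`pi/4 * w * h`). A single soma fills its
#' bounding ellipse; a dumbbell of two co-active somas does not. This is a
#' crude stand-in for the shape prior a trained instance-segmentation
#' detector provides.
#'
#' @param min_px,max_px,rel_thresh see [baseline_blob_detector].
#' @param min_fill minimum fill fraction of the bounding ellipse
#'   (default 0.6; set to 0 to disable).
#' @return a `detector`.
#' @export
blob_detector <- function(min_px = 30, max_px = 500, rel_thresh = 0.3,
                          min_fill = 0.6) {
  detector(function(frame) {
    dets <- baseline_blob_detector(frame, min_px, max_px, rel_thresh)
    Filter(function(cand) {
      sel <- which(cand$mask, arr.ind = TRUE)
      bb <- (diff(range(sel[, 1])) + 1) * (diff(range(sel[, 2])) + 1)
      nrow(sel) >= min_fill * (pi / 4) * bb
    }, dets)
  }, name = "blob")
}

#' Accept or reject one candidate footprint
#'
#' A candidate is accepted iff (1) its confidence exceeds `cmin`; (2) the
#' cosine similarity of its weighted footprint against every accepted
#' footprint is below `treal`; (3) the cosine similarity of its binary
#' support against every accepted support is below `tbin`; and (4) its mask
#' cosine against every other detection in the same frame is at most
#' `max_frame_overlap` (well-isolated in its frame).
#'
#' @param candidate list with `image` (numeric d-vector, zero off-mask) and
#'   `mask` (logical d-vector) in unrolled full-FOV coordinates, plus
#'   `confidence`.
#' @param accepted_images d x N matrix (or NULL) of accepted footprints.
#' @param accepted_masks d x N 0/1 matrix (or NULL) of accepted supports.
#' @param params a [detection_params].
#' @param same_frame_masks d x M 0/1 matrix (or NULL) of the other
#'   detections in the candidate's frame.
#' @return list with `accept` (logical) and `reason` (`"accepted"`,
#'   `"confidence"`, `"treal"`, `"tbin"`, or `"frame_overlap"`).
#' @export
filter_candidate <- function(candidate, accepted_images, accepted_masks,
                             params, same_frame_masks = NULL) {
  if (candidate$confidence <= params$cmin) {
    return(list(accept = FALSE, reason = "confidence"))
  }
  if (max_cosine_vs_columns(candidate$image, accepted_images) >= params$treal) {
    return(list(accept = FALSE, reason = "treal"))
  }
  m <- as.numeric(candidate$mask)
  if (max_cosine_vs_columns(m, accepted_masks) >= params$tbin) {
    return(list(accept = FALSE, reason = "tbin"))
  }
  if (max_cosine_vs_columns(m, same_frame_masks) > params$max_frame_overlap) {
    return(list(accept = FALSE, reason = "frame_overlap"))
  }
  list(accept = TRUE, reason = "accepted")
}

# Non-overlapping detection patch origins covering [1, n] with side p
# (last patch shifted to touch the border).
detection_patch_starts <- function(n, p) {
  s <- seq.int(1L, max(1L, n - p + 1L), by = p)
  if (s[length(s)] + p - 1L < n) s <- c(s, n - p + 1L)
  unique(s)
}

#' Run patchwise detection on a sparsened movie
#'
#' For every detection patch: the top-`n` brightest frames (patch-local
#' brightness) are rendered as rectified dense images on the padded patch,
#' the detector proposes candidate masks, and candidates are filtered
#' locally by the [filter_candidate] rules. Patch lists are then merged
#' globally by re-running the filter across patches in a deterministic
#' order (patch index, then frame brightness). Accepted candidate images,
#' normalized to unit maximum, become the columns of `A_init`.
#'
#' @param sparse a `sparse_movie`.
#' @param det a [detector] (default [blob_detector]).
#' @param params a [detection_params].
#' @return a `detection_result`: `A_init` (sparse `d x N`), `masks`
#'   (logical `d x N`), and `candidates` (data.frame of provenance:
#'   patch, frame, confidence, reason).
#' @export
run_patchwise_detection <- function(sparse, det = blob_detector(),
                                    params = detection_params()) {
  stopifnot(inherits(sparse, "sparse_movie"), inherits(det, "detector"),
            inherits(params, "detection_params"))
  pmd <- sparse$pmd
  H <- pmd$height; W <- pmd$width; d <- H * W
  ys <- detection_patch_starts(H, min(params$patch_size, H))
  xs <- detection_patch_starts(W, min(params$patch_size, W))
  pad <- params$patch_pad
  local_accepted <- list()   # per global order: candidate records
  prov <- list()
  patch_id <- 0L
  for (y0 in ys) for (x0 in xs) {
    patch_id <- patch_id + 1L
    yy <- y0:min(y0 + params$patch_size - 1L, H)
    xx <- x0:min(x0 + params$patch_size - 1L, W)
    core_pix <- as.integer(outer(xx, (yy - 1L) * W, `+`))
    # padded rendering window
    yyp <- max(1L, y0 - pad):min(H, max(yy) + pad)
    xxp <- max(1L, x0 - pad):min(W, max(xx) + pad)
    pad_pix <- as.integer(outer(xxp, (yyp - 1L) * W, `+`))
    ph <- length(yyp); pw <- length(xxp)
    ord <- rank_frames_by_brightness(sparse, core_pix)
    top <- ord[seq_len(min(params$n, length(ord)))]
    Xf <- render_sparse_frames(sparse, pad_pix, top)
    acc_img <- NULL; acc_mask <- NULL
    for (fi in seq_along(top)) {
      img <- matrix(Xf[, fi], nrow = ph, ncol = pw, byrow = TRUE)
      dets <- det$detect(img)
      if (length(dets) == 0) next
      # drop masks clipped by the render window: a cell cut off at the
      # padded border is seen whole from the neighboring patch instead
      # (borders that coincide with the FOV edge are genuine)
      dets <- Filter(function(cand) {
        sel <- which(cand$mask)
        ry <- ((sel - 1L) %% ph) + 1L
        rx <- ((sel - 1L) %/% ph) + 1L
        !((any(ry == 1L) && yyp[1] > 1L) ||
            (any(ry == ph) && yyp[ph] < H) ||
            (any(rx == 1L) && xxp[1] > 1L) ||
            (any(rx == pw) && xxp[pw] < W))
      }, dets)
      if (length(dets) == 0) next
      # embed each detection in the full FOV
      embedded <- lapply(dets, function(cand) {
        maskv <- logical(d)
        imgv <- numeric(d)
        sel <- which(cand$mask)
        ry <- ((sel - 1L) %% ph) + 1L
        rx <- ((sel - 1L) %/% ph) + 1L
        gidx <- (yyp[ry] - 1L) * W + xxp[rx]
        maskv[gidx] <- TRUE
        imgv[gidx] <- img[sel]
        list(mask = maskv, image = imgv, confidence = cand$confidence,
             frame = top[fi], patch = patch_id)
      })
      mask_mat <- vapply(embedded, function(e) as.numeric(e$mask), numeric(d))
      for (ci in seq_along(embedded)) {
        cand <- embedded[[ci]]
        same <- if (length(embedded) > 1) {
          mask_mat[, -ci, drop = FALSE]
        } else NULL
        res <- filter_candidate(cand, acc_img, acc_mask, params, same)
        prov[[length(prov) + 1L]] <-
          data.frame(patch = patch_id, frame = cand$frame,
                     confidence = cand$confidence, reason = res$reason,
                     stage = "patch")
        if (res$accept) {
          acc_img <- cbind(acc_img, cand$image)
          acc_mask <- cbind(acc_mask, as.numeric(cand$mask))
          local_accepted[[length(local_accepted) + 1L]] <- cand
        }
      }
    }
  }
  # global merge across patches: deterministic order already established
  # (patch index, then frame brightness within patch)
  g_img <- NULL; g_mask <- NULL
  kept <- list()
  for (cand in local_accepted) {
    res <- filter_candidate(cand, g_img, g_mask, params, NULL)
    prov[[length(prov) + 1L]] <-
      data.frame(patch = cand$patch, frame = cand$frame,
                 confidence = cand$confidence, reason = res$reason,
                 stage = "global")
    if (res$accept) {
      g_img <- cbind(g_img, cand$image / max(cand$image))
      g_mask <- cbind(g_mask, as.numeric(cand$mask))
      kept[[length(kept) + 1L]] <- cand
    }
  }
  candidates <- if (length(prov)) do.call(rbind, prov) else
    data.frame(patch = integer(0), frame = integer(0),
               confidence = numeric(0), reason = character(0),
               stage = character(0))
  if (is.null(g_img)) {
    warning("no candidates accepted; A_init is empty")
    A_init <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(d, 0))
    masks <- matrix(FALSE, d, 0)
  } else {
    A_init <- methods::as(methods::as(Matrix::Matrix(g_img, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")
    masks <- g_mask > 0
  }
  structure(list(A_init = A_init, masks = masks, candidates = candidates,
                 height = H, width = W),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d accepted footprint(s), %d candidate record(s)\n",
              ncol(x$A_init), nrow(x$candidates)))
  invisible(x)
}
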