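# Constrained NMF demixing on the compressed representation: hierarchical
# alternating least squares (HALS) updates of footprints and traces with
# frozen support masks, a simplified static + constant-weight ring
# background, and a superpixel multi-pass on the residual. Every heavy
# quantity is computed from the (U, V) factors and small Gram matrices; the
# dense d x T movie is never allocated.

#' Neuron set container
#'
#' @param A `d x N` nonnegative footprint matrix (dense).
#' @param C `N x T` nonnegative trace matrix.
#' @param supports logical `d x N` support masks; footprints are zero
#'   off-support.
#' @return a `neuron_set`.
#' @export
neuron_set <- function(A, C, supports) {
  A <- as.matrix(A); C <- as.matrix(C)
  stopifnot(ncol(A) == nrow(C), all(A >= 0), all(C >= 0),
            nrow(A) == nrow(supports), ncol(A) == ncol(supports))
  A[!supports] <- 0
  structure(list(A = A, C = C, supports = supports), class = "neuron_set")
}

#' @export
print.neuron_set <- function(x, ...) {
  cat(sprintf("<neuron_set> %d component(s), T = %d\n", ncol(x$A), ncol(x$C)))
  invisible(x)
}

#' Demixing configuration
#'
#' @param n_passes demixing passes (each pass = HALS/background iterations
#'   followed by a superpixel search of the residual); default 2.
#' @param n_outer (HALS + background) iterations per pass; default 3.
#' @param hals_sweeps HALS sweeps per iteration; default 2.
#' @param init_sweeps HALS sweeps for the temporal initialization;
#'   default 5.
#' @param ring_radius Chebyshev radius of the background ring in pixels
#'   (about 1.5x the median soma radius); default 8.
#' @param corr_thresh residual correlation threshold for superpixel edges;
#'   default 0.7.
#' @param min_size minimum superpixel size in pixels; default 20.
#' @param min_trace_sd minimum residual trace standard deviation (in
#'   noise-normalized units) for a pixel to join a superpixel; default
#'   0.15. Correlation is scale-invariant, so without this floor a well-fit
#'   residual seeds spurious components from subspace-correlated noise.
#' @param support_dilate dilation radius applied to detection masks to
#'   form the frozen HALS supports; default 2.
#' @param prune_rel components with footprint-times-trace norm below this
#'   fraction of the largest are dropped; default 1e-6.
#' @param filter_params [detection_params] used to gate superpixel
#'   candidates against existing components.
#' @return a `demix_config` list.
#' @export
demix_config <- function(n_passes = 2, n_outer = 3, hals_sweeps = 2,
                         init_sweeps = 5, ring_radius = 8, corr_thresh = 0.7,
                         min_size = 20, min_trace_sd = 0.15,
                         support_dilate = 2, prune_rel = 1e-6,
                         filter_params = detection_params()) {
  stopifnot(n_passes >= 0, n_outer >= 1, hals_sweeps >= 1, ring_radius >= 1,
            corr_thresh > 0, corr_thresh < 1, min_size >= 1)
  structure(list(n_passes = n_passes, n_outer = n_outer,
                 hals_sweeps = hals_sweeps, init_sweeps = init_sweeps,
                 ring_radius = ring_radius, corr_thresh = corr_thresh,
                 min_size = min_size, min_trace_sd = min_trace_sd,
                 support_dilate = support_dilate, prune_rel = prune_rel,
                 filter_params = filter_params),
            class = "demix_config")
}

# Empty background model: no fluctuating term, and a static term equal to
# the stored per-pixel means, so that "no background" makes the demixing
# target exactly the mean-removed denoised movie U V (baselines are
# background by definition and must not leak into the traces).
empty_background <- function(pmd) {
  structure(list(b = pmd$means,
                 Q = matrix(0, pmd$K, ncol(pmd$V)),
                 ring_weights = numeric(nrow(pmd$U)),
                 ring_radius = NA_real_),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> ring radius %s, %d pixel(s) with nonzero ring weight\n",
              format(x$ring_radius), sum(x$ring_weights > 0)))
  invisible(x)
}

#' Demixing objective
#'
#' Computes `||U V + means - A C - B||_F^2` (with
#' `B = b 1' + U Q`) from Gram matrices, without forming any `d x T`
#' array.
#'
#' @param pmd a [decompose_pmd] result.
#' @param neurons a [neuron_set].
#' @param background a background model (or NULL for none).
#' @return scalar objective value.
#' @export
demix_objective <- function(pmd, neurons, background = NULL) {
  if (is.null(background)) background <- empty_background(pmd)
  W <- pmd$V - background$Q
  delta <- pmd$means - background$b
  A <- neurons$A; C <- neurons$C
  Tn <- ncol(pmd$V)
  UtU <- as.matrix(Matrix::crossprod(pmd$U))
  t1 <- sum((UtU %*% W) * W)
  Ud <- as.numeric(Matrix::crossprod(pmd$U, delta))
  if (ncol(A) > 0) {
    AU <- as.matrix(Matrix::crossprod(Matrix::Matrix(A, sparse = TRUE), pmd$U))
    AtA <- crossprod(A)
    t2 <- sum((AU %*% W) * C)
    t3 <- sum((AtA %*% C) * C)
    t4b <- sum(as.numeric(crossprod(A, delta)) * rowSums(C))
  } else {
    t2 <- 0; t3 <- 0; t4b <- 0
  }
  t4a <- sum(Ud * rowSums(W))
  t1 - 2 * t2 + t3 + 2 * t4a - 2 * t4b + Tn * sum(delta^2)
}

# One HALS sweep over traces (C), background fixed. Returns updated C.
hals_sweep_C <- function(pmd, A, C, background) {
  W <- pmd$V - background$Q
  delta <- pmd$means - background$b
  As <- Matrix::Matrix(A, sparse = TRUE)
  AU <- as.matrix(Matrix::crossprod(As, pmd$U))      # N x K
  E <- AU %*% W                                      # N x T
  Ad <- as.numeric(crossprod(A, delta))
  AtA <- crossprod(A)
  for (i in seq_len(nrow(C))) {
    if (AtA[i, i] <= 0) next
    r <- E[i, ] + Ad[i] - as.numeric(AtA[i, , drop = FALSE] %*% C)
    C[i, ] <- pmax(0, C[i, ] + r / AtA[i, i])
  }
  C
}

# One HALS sweep over footprints (A), supports frozen, background fixed.
hals_sweep_A <- function(pmd, A, C, supports, background) {
  W <- pmd$V - background$Q
  delta <- pmd$means - background$b
  VC <- W %*% t(C)                                   # K x N
  UVC <- as.matrix(pmd$U %*% VC)                     # d x N
  sC <- rowSums(C)
  CC <- tcrossprod(C)
  for (i in seq_len(ncol(A))) {
    if (CC[i, i] <= 0) next
    u <- UVC[, i] + delta * sC[i] - as.numeric(A %*% CC[, i])
    a <- pmax(0, A[, i] + u / CC[i, i])
    a[!supports[, i]] <- 0
    A[, i] <- a
  }
  A
}

# Drop collapsed components (||a||*||c|| below prune_rel of the largest).
prune_components <- function(neurons, prune_rel = 1e-6) {
  if (ncol(neurons$A) == 0) return(neurons)
  en <- sqrt(colSums(neurons$A^2)) * sqrt(rowSums(neurons$C^2))
  keep <- en >= prune_rel * max(en)
  if (all(keep)) return(neurons)
  neuron_set(neurons$A[, keep, drop = FALSE],
             neurons$C[keep, , drop = FALSE],
             neurons$supports[, keep, drop = FALSE])
}

#' Initialize temporal traces by nonnegative regression
#'
#' Given initial footprints, estimates `C` by HALS sweeps on
#' `min_{C >= 0} ||U V + means - A C||_F^2`, computed through the
#' factorized Gram quantities. All-zero footprint columns are dropped with
#' a warning.
#'
#' @param pmd a [decompose_pmd] result.
#' @param A_init `d x N` nonnegative footprints (sparse or dense).
#' @param masks optional logical `d x N` supports (defaults to
#'   `A_init > 0`).
#' @param n_sweeps HALS sweeps (default 5).
#' @param support_dilate dilation radius for the stored supports
#'   (default 2).
#' @return a [neuron_set] with the estimated `C`.
#' @export
initialize_temporal <- function(pmd, A_init, masks = NULL, n_sweeps = 5,
                                support_dilate = 2) {
  A <- as.matrix(A_init)
  if (ncol(A) == 0) stop("A_init is empty")
  if (is.null(masks)) masks <- A > 0
  zero <- colSums(A) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero footprint column(s) dropped")
    A <- A[, !zero, drop = FALSE]
    masks <- masks[, !zero, drop = FALSE]
    if (ncol(A) == 0) {
      return(neuron_set(A, matrix(0, 0, ncol(pmd$V)), masks))
    }
  }
  supports <- dilate_supports(masks, pmd$height, pmd$width, support_dilate)
  C <- matrix(0, ncol(A), ncol(pmd$V))
  bg <- empty_background(pmd)
  for (s in seq_len(n_sweeps)) C <- hals_sweep_C(pmd, A, C, bg)
  neuron_set(A, C, supports)
}

# Dilate each mask column by `r` pixels (disc) within the FOV.
dilate_supports <- function(masks, H, W, r) {
  if (r <= 0 || ncol(masks) == 0) return(masks)
  out <- masks
  for (i in seq_len(ncol(masks))) {
    img <- unroll_to_image(masks[, i], H, W) > 0
    out[, i] <- image_to_unrolled(dilate_mask(img, r)) > 0
  }
  out
}

#' Run HALS sweeps on footprints and traces
#'
#' Each sweep performs exact per-component nonnegative coordinate updates
#' of every trace then every footprint (restricted to its frozen support)
#' against the background-subtracted target; the objective
#' `||U V + means - A C - B||^2` is therefore non-increasing across sweeps.
#' Collapsed components are pruned.
#'
#' @param pmd a [decompose_pmd] result.
#' @param neurons a [neuron_set].
#' @param background a background model (NULL for none), held fixed.
#' @param n_sweeps number of sweeps (default 2).
#' @param prune_rel pruning threshold (see [demix_config]).
#' @return a [neuron_set] with attribute `"objective"`: the objective after
#'   every sweep.
#' @export
hals_iterate <- function(pmd, neurons, background = NULL, n_sweeps = 2,
                         prune_rel = 1e-6) {
  stopifnot(inherits(pmd, "pmd"), inherits(neurons, "neuron_set"))
  if (is.null(background)) background <- empty_background(pmd)
  obj <- numeric(0)
  A <- neurons$A; C <- neurons$C
  for (s in seq_len(n_sweeps)) {
    C <- hals_sweep_C(pmd, A, C, background)
    A <- hals_sweep_A(pmd, A, C, neurons$supports, background)
    if (!all(is.finite(A)) || !all(is.finite(C))) {
      bad <- which(!is.finite(colSums(A) + rowSums(C)))[1]
      stop("non-finite HALS update in component ", bad)
    }
    ns <- neuron_set(A, C, neurons$supports)
    obj <- c(obj, demix_objective(pmd, ns, background))
  }
  out <- prune_components(neuron_set(A, C, neurons$supports), prune_rel)
  attr(out, "objective") <- obj
  out
}

# Sparse ring-averaging operator: row i averages the pixels at Chebyshev
# distance `radius` from pixel i, excluding pixels in `exclude` (logical d),
# renormalized by the count of remaining ring pixels (zero row if none).
ring_operator <- function(H, W, radius, exclude) {
  offs <- list()
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (max(abs(dy), abs(dx)) == radius) offs[[length(offs) + 1L]] <- c(dy, dx)
  }
  yy <- rep(seq_len(H), each = W)
  xx <- rep(seq_len(W), times = H)
  idx <- (yy - 1L) * W + xx
  ii <- list(); jj <- list()
  for (o in offs) {
    y2 <- yy + o[1]; x2 <- xx + o[2]
    ok <- y2 >= 1L & y2 <= H & x2 >= 1L & x2 <= W
    j <- (y2[ok] - 1L) * W + x2[ok]
    keep <- !exclude[j]
    ii[[length(ii) + 1L]] <- idx[ok][keep]
    jj[[length(jj) + 1L]] <- j[keep]
  }
  Wr <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                             x = rep(1, length(unlist(ii))),
                             dims = c(H * W, H * W))
  cnt <- Matrix::rowSums(Wr)
  cnt[cnt == 0] <- 1
  Matrix::Diagonal(x = 1 / cnt) %*% Wr
}

#' Update the background model
#'
#' The static term is the per-pixel temporal mean of the residual
#' `U V + means - A C`. The fluctuating term uses a constant-weight ring
#' model: each pixel's neuropil trace is the average of the pixels at
#' Chebyshev distance `ring_radius`, excluding any pixel in the support of
#' `A`; a single nonnegative scalar weight per pixel is fit by 1-D least
#' squares of the pixel's static-subtracted residual trace against its
#' ring-averaged trace. The resulting fluctuating background is projected
#' onto the spatial basis `U` and stored factorized as `U Q`. All inner
#' products are computed through Gram matrices.
#'
#' Weights are capped at `w_max`: a genuinely smooth neuropil background is
#' close to its own ring average, so its weight is O(1), whereas a large
#' fitted weight means the ring is amplifying a faint copy of a signal that
#' is not background (typically an unmodeled soma), which the multi-pass
#' residual search should recover instead.
#'
#' @param pmd a [decompose_pmd] result.
#' @param neurons a [neuron_set].
#' @param ring_radius ring radius in pixels (>= 1).
#' @param w_max ring weight cap (default 2).
#' @return a `background_model`: `b` (static, length d), `Q` (`K x T`
#'   fluctuating coefficients), `ring_weights` (length d), `ring_radius`.
#' @export
update_background <- function(pmd, neurons, ring_radius = 8, w_max = 2) {
  stopifnot(inherits(pmd, "pmd"), ring_radius >= 1)
  A <- neurons$A; C <- neurons$C
  Tn <- ncol(pmd$V)
  has_A <- ncol(A) > 0
  vbar <- rowMeans(pmd$V)
  b <- pmd$means + as.numeric(pmd$U %*% vbar) -
    (if (has_A) as.numeric(A %*% rowMeans(C)) else 0)
  delta <- pmd$means - b
  supp <- if (has_A) rowSums(neurons$supports) > 0 else rep(FALSE, nrow(A))
  Wr <- ring_operator(pmd$height, pmd$width, ring_radius, supp)
  U <- pmd$U; V <- pmd$V
  Gu <- Wr %*% U                                   # sparse d x K
  eps <- as.numeric(Wr %*% delta)
  SVV <- tcrossprod(V)
  v1 <- rowSums(V)
  Gud <- as.matrix(Gu)
  num <- rowSums(as.matrix(U %*% SVV) * Gud) +
    as.numeric(U %*% v1) * eps +
    delta * as.numeric(Gu %*% v1) +
    Tn * delta * eps
  den <- rowSums(as.matrix(Gu %*% SVV) * Gud) +
    2 * eps * as.numeric(Gu %*% v1) + Tn * eps^2
  if (has_A) {
    As <- Matrix::Matrix(A, sparse = TRUE)
    Ga <- as.matrix(Wr %*% As)                     # d x N
    SVC <- V %*% t(C)                              # K x N
    SCC <- tcrossprod(C)
    c1 <- rowSums(C)
    num <- num - rowSums(as.matrix(U %*% SVC) * Ga) -
      rowSums((A %*% t(SVC)) * Gud) +
      rowSums((A %*% SCC) * Ga) -
      as.numeric(A %*% c1) * eps -
      delta * as.numeric(Ga %*% c1)
    den <- den - 2 * rowSums(as.matrix(Gu %*% SVC) * Ga) +
      rowSums((Ga %*% SCC) * Ga) - 2 * eps * as.numeric(Ga %*% c1)
  }
  w <- ifelse(den > 1e-12, pmin(pmax(0, num / den), w_max), 0)
  # project diag(w) %*% Wr %*% (residual) onto U, keeping K x T factors
  M1 <- as.matrix(Matrix::crossprod(U, w * Gu))    # K x K
  rhs <- M1 %*% V
  m3 <- as.numeric(Matrix::crossprod(U, w * eps))
  rhs <- rhs + outer(m3, rep(1, Tn))
  if (has_A) {
    M2 <- as.matrix(Matrix::crossprod(U, w * Ga))  # K x N
    rhs <- rhs - M2 %*% C
  }
  Q <- solve_gram(U, rhs)
  structure(list(b = b, Q = Q, ring_weights = w, ring_radius = ring_radius),
            class = "background_model")
}

#' Search the residual for missed components via superpixels
#'
#' The residual `U V + means - A C - B` is kept factorized; temporal
#' correlations between 4-neighbor pixel residual traces are computed
#' through Gram matrices. Edges with correlation above `corr_thresh`
#' (between pixels whose residual trace sd exceeds `min_trace_sd`) are
#' collected; connected components with at least `min_size` pixels become
#' superpixels. Each superpixel is factorized into a nonnegative rank-1
#' `(a, c)` pair by rectified power iteration, and candidates must pass the
#' [filter_candidate] cosine rules against the existing components.
#'
#' @param pmd a [decompose_pmd] result.
#' @param neurons a [neuron_set] (may have zero components).
#' @param background a background model (NULL for none).
#' @param config a [demix_config].
#' @return list of candidates, each with `a` (d-vector, unit max), `c`
#'   (T-vector), `mask` (logical d).
#' @export
superpixel_residual_pass <- function(pmd, neurons, background = NULL,
                                     config = demix_config()) {
  if (is.null(background)) background <- empty_background(pmd)
  U <- pmd$U
  d <- nrow(U); Tn <- ncol(pmd$V)
  Wt <- pmd$V - background$Q
  delta <- pmd$means - background$b
  has_A <- ncol(neurons$A) > 0
  Hm <- if (has_A) {
    Matrix::cbind2(U, Matrix::Matrix(-neurons$A, sparse = TRUE))
  } else U
  G <- if (has_A) rbind(Wt, neurons$C) else Wt
  Gc <- G - rowMeans(G)
  Sig <- tcrossprod(Gc)
  M <- as.matrix(Hm %*% Sig)
  Hd <- as.matrix(Hm)
  v <- rowSums(M * Hd)                      # unnormalized trace variances
  sd_ok <- sqrt(pmax(v, 0) / (Tn - 1)) >= config$min_trace_sd
  H <- pmd$height; W <- pmd$width
  edge_list <- list()
  # right neighbors: (y, x) - (y, x+1); row-major index i and i+1
  yy <- rep(seq_len(H), each = W - 1L)
  xx <- rep(seq_len(W - 1L), times = H)
  i1 <- (yy - 1L) * W + xx
  edge_list[[1]] <- cbind(i1, i1 + 1L)
  # down neighbors: (y, x) - (y+1, x)
  yy <- rep(seq_len(H - 1L), each = W)
  xx <- rep(seq_len(W), times = H - 1L)
  i1 <- (yy - 1L) * W + xx
  edge_list[[2]] <- cbind(i1, i1 + W)
  E <- do.call(rbind, edge_list)
  ok <- sd_ok[E[, 1]] & sd_ok[E[, 2]]
  E <- E[ok, , drop = FALSE]
  if (nrow(E) == 0) return(list())
  cv <- rowSums(M[E[, 1], , drop = FALSE] * Hd[E[, 2], , drop = FALSE])
  cr <- cv / sqrt(v[E[, 1]] * v[E[, 2]])
  E <- E[is.finite(cr) & cr > config$corr_thresh, , drop = FALSE]
  if (nrow(E) == 0) return(list())
  g <- igraph::graph_from_edgelist(matrix(as.character(E), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  pix_ids <- as.integer(igraph::V(g)$name)
  cands <- list()
  sizes <- tabulate(comp$membership)
  order_comp <- order(-sizes)
  acc_img <- if (has_A) neurons$A else NULL
  acc_mask <- if (has_A) (neurons$supports * 1) else NULL
  fp <- config$filter_params
  for (ci in order_comp) {
    if (sizes[ci] < config$min_size) next
    pix <- sort(pix_ids[comp$membership == ci])
    X <- as.matrix(Hm[pix, , drop = FALSE] %*% G) + delta[pix]
    X[X < 0] <- 0
    cc <- pmax(colMeans(X), 0)
    a <- numeric(length(pix))
    for (it in 1:10) {
      s2 <- sum(cc^2); if (s2 == 0) break
      a <- pmax(as.numeric(X %*% cc), 0) / s2
      s2 <- sum(a^2); if (s2 == 0) break
      cc <- pmax(as.numeric(crossprod(X, a)), 0) / s2
    }
    if (max(a) <= 0 || max(cc) <= 0) next
    cc <- cc * max(a)
    a <- a / max(a)
    av <- numeric(d); av[pix] <- a
    mk <- av > 0
    res <- filter_candidate(list(image = av, mask = mk, confidence = 1),
                            acc_img, acc_mask, fp, NULL)
    if (!res$accept) next
    acc_img <- cbind(acc_img, av)
    acc_mask <- cbind(acc_mask, as.numeric(mk))
    cands[[length(cands) + 1L]] <- list(a = av, c = cc, mask = mk)
  }
  cands
}

#' Demix a compressed movie by multi-pass constrained NMF
#'
#' Runs the full demixing loop: temporal initialization from the detected
#' footprints (pass 1), alternating HALS and background updates, then a
#' superpixel search of the residual whose accepted candidates join the
#' component set for the next pass. Stops after `n_passes` passes or as
#' soon as a superpixel pass adds nothing.
#'
#' @param pmd a [decompose_pmd] result.
#' @param A_init `d x N` nonnegative initial footprints (may have zero
#'   columns for a superpixel-only run).
#' @param masks optional logical `d x N` detection masks (defaults to
#'   `A_init > 0`).
#' @param config a [demix_config].
#' @return a `demix_result`: `neurons` ([neuron_set]), `background`,
#'   `objective` (per HALS sweep, concatenated), `n_passes_run`.
#' @export
run_localnmf <- function(pmd, A_init, masks = NULL, config = demix_config()) {
  stopifnot(inherits(pmd, "pmd"), inherits(config, "demix_config"))
  A <- as.matrix(A_init)
  d <- pmd$height * pmd$width
  if (is.null(masks)) masks <- A > 0
  empty_ns <- function() {
    neuron_set(matrix(0, d, 0), matrix(0, 0, ncol(pmd$V)),
               matrix(FALSE, d, 0))
  }
  neurons <- if (ncol(A) > 0) {
    initialize_temporal(pmd, A, masks, n_sweeps = config$init_sweeps,
                        support_dilate = config$support_dilate)
  } else {
    empty_ns()
  }
  background <- empty_background(pmd)
  objective <- numeric(0)
  passes <- 0L
  if (config$n_passes == 0) {
    return(structure(list(neurons = neurons, background = background,
                          objective = objective, n_passes_run = 0L),
                     class = "demix_result"))
  }
  for (p in seq_len(config$n_passes)) {
    passes <- p
    for (it in seq_len(config$n_outer)) {
      if (ncol(neurons$A) > 0) {
        neurons <- hals_iterate(pmd, neurons, background,
                                n_sweeps = config$hals_sweeps,
                                prune_rel = config$prune_rel)
        objective <- c(objective, attr(neurons, "objective"))
      }
      background <- update_background(pmd, neurons,
                                      ring_radius = config$ring_radius)
    }
    if (p == config$n_passes) break
    cands <- superpixel_residual_pass(pmd, neurons, background, config)
    if (length(cands) == 0) break
    Anew <- vapply(cands, function(x) x$a, numeric(d))
    Cnew <- t(vapply(cands, function(x) x$c, numeric(ncol(pmd$V))))
    Mnew <- vapply(cands, function(x) x$mask, logical(d))
    supp_new <- dilate_supports(Mnew, pmd$height, pmd$width,
                                config$support_dilate)
    neurons <- neuron_set(cbind(neurons$A, Anew), rbind(neurons$C, Cnew),
                          cbind(neurons$supports, supp_new))
  }
  if (ncol(neurons$A) == 0) {
    warning("no components found (empty initialization and no superpixels)")
  }
  structure(list(neurons = neurons, background = background,
                 objective = objective, n_passes_run = passes),
            class = "demix_result")
}

#' @export
print.demix_result <- function(x, ...) {
  cat(sprintf("<demix_result> %d component(s), %d pass(es), final objective %.4g\n",
              ncol(x$neurons$A), x$n_passes_run,
              if (length(x$objective)) tail(x$objective, 1) else NA))
  invisible(x)
}
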