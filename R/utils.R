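# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Cosine similarity between two nonnegative (or general) vectors; 0 when
# either has zero norm.
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# Max cosine similarity of vector `x` against the columns of matrix `m`
# (returns 0 for zero columns or empty m).
max_cosine_vs_columns <- function(x, m) {
  if (is.null(m) || NCOL(m) == 0) return(0)
  m <- as.matrix(m)
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(0)
  cn <- sqrt(colSums(m^2))
  cn[cn == 0] <- Inf
  max(as.numeric(crossprod(m, x)) / (nx * cn))
}

# Binary dilation of a logical H x W mask by a disc of radius `r` pixels.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  out <- mask
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    if (dy * dy + dx * dx > r * r) next
    ys <- max(1, 1 + dy):min(H, H + dy)
    xs <- max(1, 1 + dx):min(W, W + dx)
    out[ys, xs] <- out[ys, xs] | mask[ys - dy, xs - dx]
  }
  out
}

# Separable Gaussian blur of an H x W image (sd in pixels, zero-padded).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    # convolve each column with k, zero padding
    n <- nrow(m)
    mp <- rbind(matrix(0, hw, ncol(m)), m, matrix(0, hw, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_len(2 * hw + 1)) {
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# 8-connected components of a logical H x W mask. Returns an integer matrix
# of labels (0 = background), labels ordered by first (column-major) pixel.
label_components_8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  pos <- integer(H * W)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  # neighbors at offsets (+1,0), (0,+1), (+1,+1), (-1,+1) cover all 8-conn pairs
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * H + r2[ok]
    hit <- pos[j] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(pos[idx[ok]][hit], pos[j][hit]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel by order of first occurrence for determinism
  first <- match(unique(comp), comp)
  rel <- integer(max(comp))
  rel[comp[sort(first)]] <- seq_along(first)
  lab[idx] <- rel[comp]
  lab
}

# Row-major unrolling helpers: pixel (row y, col x), both 1-based, maps to
# index (y-1)*W + x in the unrolled d-vector.
pixel_index <- function(y, x, W) (y - 1L) * W + x

# Reshape an unrolled d-vector (row-major) into an H x W matrix.
unroll_to_image <- function(v, H, W) {
  matrix(v, nrow = H, ncol = W, byrow = TRUE)
}

# Flatten an H x W image to the row-major unrolled d-vector.
image_to_unrolled <- function(img) {
  as.numeric(t(img))
}
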