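# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no data files.

# Exact periodic translation of an image (content moves by (dy, dx)) via a
# Fourier phase ramp; used as the independent oracle for registration.
fourier_shift <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  fy <- c(0:floor((H - 1) / 2), -(ceiling((H - 1) / 2):1))
  fx <- c(0:floor((W - 1) / 2), -(ceiling((W - 1) / 2):1))
  ph <- exp(-2i * pi * (outer(fy, rep(1, W)) * dy / H +
                          outer(rep(1, H), fx) * dx / W))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (H * W)
}

# Integer circular shift of an image (content moves by (dy, dx)).
roll_shift <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  img[((seq_len(H) - 1 - dy) %% H) + 1, ((seq_len(W) - 1 - dx) %% W) + 1]
}

# Independent constrained-QP oracle for the sparse AR(1) deconvolution
# problem: parameterize c = L s with L[t, k] = g^(t-k) (t >= k) and solve
# the box-constrained quadratic with L-BFGS-B. Returns the objective value.
oasis_qp_oracle <- function(y, g, lam) {
  Tn <- length(y)
  L <- stats::toeplitz(g^(0:(Tn - 1)))
  L[upper.tri(L)] <- 0
  fn <- function(s) {
    cv <- as.numeric(L %*% s)
    0.5 * sum((cv - y)^2) + lam * sum(s)
  }
  gr <- function(s) {
    cv <- as.numeric(L %*% s)
    as.numeric(crossprod(L, cv - y)) + lam
  }
  o <- stats::optim(rep(0.1, Tn), fn, gr, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 1e1))
  o$value
}

# Objective of the deconvolution problem at a given c (for comparing the
# active-set solution with the oracle).
oasis_objective_at <- function(cvec, y, g, lam) {
  Tn <- length(y)
  s <- c(cvec[1], cvec[-1] - g * cvec[-Tn])
  0.5 * sum((cvec - y)^2) + lam * sum(s)
}

# A tiny deterministic movie with `n` well-separated soma-like neurons
# (chord-length profile of a projected sphere, as a Bessel PSF produces)
# firing transients at distinct frames, plus white noise.
# Returns list(movie, A (d x n), C (n x T), centers).
separated_neuron_movie <- function(n = 5, H = 64, W = 64, Tn = 300,
                                   amp = 8, radius = 5, noise_sd = 1,
                                   g = 0.9, seed = 7) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  d <- H * W
  # centers on a coarse grid, well separated
  grid <- expand.grid(y = round(seq(12, H - 12, length.out = ceiling(sqrt(n)))),
                      x = round(seq(12, W - 12, length.out = ceiling(sqrt(n)))))
  centers <- grid[seq_len(n), ]
  A <- matrix(0, d, n)
  for (i in seq_len(n)) {
    yy <- matrix(rep(seq_len(H), times = W), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)
    img <- sqrt(pmax(1 - ((yy - centers$y[i])^2 + (xx - centers$x[i])^2) /
                       radius^2, 0))
    img[img < 0.05] <- 0
    A[, i] <- as.numeric(t(img))
  }
  C <- matrix(0, n, Tn)
  t0 <- round(seq(20, Tn - 40, length.out = n))
  for (i in seq_len(n)) {
    s <- numeric(Tn); s[t0[i]] <- amp; s[min(Tn, t0[i] + 97)] <- amp * 0.8
    C[i, ] <- as.numeric(stats::filter(s, g, method = "recursive"))
  }
  Y <- withr_seed(A %*% C + matrix(rnorm(d * Tn, sd = noise_sd), d, Tn))
  list(movie = densedemix::movie(Y, H, W), A = A, C = C, centers = centers,
       spike_frames = t0)
}

# All permutations of 1..n as a (n! x n) matrix (for exhaustive matching
# oracles on small instances).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# Construct a `pmd` object directly from given factors (bypassing the SVD)
# so that factor-level operations can be tested against exact expectations.
fake_pmd <- function(U, V, H, W, means = NULL) {
  U <- methods::as(methods::as(Matrix::Matrix(U, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(means)) means <- numeric(nrow(U))
  structure(list(U = U, V = V, means = means,
                 layout = NULL, K = ncol(U), patch_of = integer(ncol(U)),
                 height = H, width = W),
            class = "pmd")
}
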