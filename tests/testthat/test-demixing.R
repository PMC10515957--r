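# HALS demixing, the ring background model, and the superpixel multi-pass,
# all operating on the compressed factors.

noiseless_fixture <- function(n = 4, seed = 41, H = 48, W = 48, Tn = 200) {
  fx <- separated_neuron_movie(n = n, H = H, W = W, Tn = Tn, noise_sd = 0,
                               seed = seed)
  pmd <- decompose_pmd(fx$movie)
  list(fx = fx, pmd = pmd)
}

test_that("temporal initialization recovers traces from true footprints", {
  z <- noiseless_fixture()
  ns <- initialize_temporal(z$pmd, z$fx$A)
  # the target is the mean-removed denoised movie, so for disjoint
  # noiseless neurons the solution is the baseline-removed rectified truth
  # (up to sub-noise-edge slivers the adaptive rank selection discards);
  # the static background carries the baseline
  for (i in seq_len(4)) {
    expected <- pmax(z$fx$C[i, ] - mean(z$fx$C[i, ]), 0)
    expect_lt(max(abs(ns$C[i, ] - expected)) / max(expected), 0.02)
    expect_gt(cor(ns$C[i, ], expected), 0.999)
    expect_gt(cor(ns$C[i, ], z$fx$C[i, ]), 0.98)
  }
  # single neuron with orthonormal-column footprint: one sweep gives the
  # rectified closed form a' U V
  a <- z$fx$A[, 1, drop = FALSE]
  a <- a / sqrt(sum(a^2))
  ns1 <- initialize_temporal(z$pmd, a, n_sweeps = 1)
  M_a <- as.numeric(crossprod(a, as.matrix(z$pmd$U %*% z$pmd$V)))
  expect_equal(ns1$C[1, ], pmax(M_a, 0), tolerance = 1e-8)
  # all-zero footprint columns are dropped with a warning
  expect_warning(ns0 <- initialize_temporal(z$pmd, cbind(z$fx$A, 0)),
                 "all-zero")
  expect_equal(ncol(ns0$A), 4)
})

test_that("HALS is monotone, nonnegative, and fixed at an optimum", {
  set.seed(42)
  for (rep in 1:4) {
    d <- 30 * 30; N <- 3; Tn <- 60
    U <- matrix(rnorm(d * 12), d, 12)
    pmd <- fake_pmd(U, matrix(rnorm(12 * Tn), 12, Tn), 30, 30)
    A0 <- matrix(runif(d * N) * (runif(d * N) > 0.8), d, N)
    ns <- neuron_set(A0, matrix(runif(N * Tn), N, Tn), A0 > 0)
    out <- hals_iterate(pmd, ns, n_sweeps = 4)
    obj <- attr(out, "objective")
    expect_true(all(diff(obj) <= 1e-6 * abs(obj[-length(obj)])))
    expect_true(all(out$A >= 0))
    expect_true(all(out$C >= 0))
  }
  # disjoint-support noiseless optimum is a fixed point
  z <- noiseless_fixture(seed = 43)
  ns <- initialize_temporal(z$pmd, z$fx$A, n_sweeps = 30)
  one <- hals_iterate(z$pmd, ns, n_sweeps = 1)
  expect_lt(max(abs(one$C - ns$C)) / max(ns$C), 1e-3)
})

test_that("the static background absorbs means and offsets exactly", {
  z <- noiseless_fixture(seed = 44)
  ns <- initialize_temporal(z$pmd, z$fx$A, n_sweeps = 30)
  bg <- update_background(z$pmd, ns, ring_radius = 6)
  # mean identity: the per-pixel temporal mean of the full residual
  # (denoised movie minus signal minus static background) is exactly zero
  resid_means <- z$pmd$means + as.numeric(z$pmd$U %*% rowMeans(z$pmd$V)) -
    as.numeric(ns$A %*% rowMeans(ns$C)) - bg$b
  expect_lt(max(abs(resid_means)), 1e-10)
  # AC explains the fluctuations, so the ring finds nothing to fit
  expect_lt(max(bg$ring_weights), 0.2)
  # adding a global offset beta moves b by exactly beta (same neurons):
  # the per-pixel means absorb the offset and the mean identity passes it
  # straight into the static term
  m2 <- z$fx$movie; m2$data <- m2$data + 3.5
  pmd2 <- decompose_pmd(m2)
  bg2 <- update_background(pmd2, ns, ring_radius = 6)
  expect_lt(max(abs((bg2$b - bg$b) - 3.5)), 1e-6)
})

test_that("the ring model captures a smooth fluctuating background", {
  set.seed(45)
  H <- W <- 48; d <- H * W; Tn <- 200
  fx <- separated_neuron_movie(n = 3, H = H, W = W, Tn = Tn, noise_sd = 0.5,
                               seed = 45)
  yy <- matrix(rep(seq_len(H), times = W), H, W)
  xx <- t(yy)
  bg_img <- exp(-((yy - 24)^2 + (xx - 24)^2) / (2 * 20^2))
  bg_t <- 2 * pmax(sin(seq_len(Tn) / 8), 0)
  Y <- fx$movie$data + outer(as.numeric(t(bg_img)), bg_t)
  pmd <- decompose_pmd(movie(Y, H, W))
  ns <- initialize_temporal(pmd, fx$A, n_sweeps = 20)
  ns <- hals_iterate(pmd, ns, n_sweeps = 5)
  bg <- update_background(pmd, ns, ring_radius = 6)
  # residual energy off the neuron supports drops by >= 50% with the ring
  off <- rowSums(ns$supports) == 0
  resid_energy <- function(Q, b) {
    R <- as.matrix(pmd$U %*% (pmd$V - Q)) + (pmd$means - b) -
      ns$A %*% ns$C
    sum(R[off, ]^2)
  }
  e_static <- resid_energy(matrix(0, pmd$K, Tn), bg$b)
  e_ring <- resid_energy(bg$Q, bg$b)
  expect_lt(e_ring, 0.5 * e_static)
  # ring weights are zero wherever the ring has no admissible pixels
  expect_true(all(bg$ring_weights >= 0))
})

test_that("ring rows exclude footprint-support pixels", {
  H <- W <- 12
  excl <- rep(FALSE, H * W)
  excl[densedemix:::pixel_index(6, 6, W)] <- TRUE
  Wr <- densedemix:::ring_operator(H, W, 2, excl)
  expect_equal(sum(Wr[, densedemix:::pixel_index(6, 6, W)]), 0)
  # rows renormalize over the surviving ring pixels
  i <- densedemix:::pixel_index(4, 6, W)   # (6,6) lies on its radius-2 ring
  expect_equal(sum(Wr[i, ]), 1, tolerance = 1e-12)
})

test_that("superpixels ignore noise but find a withheld neuron", {
  set.seed(46)
  # pure white-noise residual: no superpixels at corr_thresh >= 0.5
  d <- 20 * 20; Tn <- 100
  pmd_n <- fake_pmd(diag(d), matrix(rnorm(d * Tn), d, Tn), 20, 20)
  ns0 <- neuron_set(matrix(0, d, 0), matrix(0, 0, Tn), matrix(FALSE, d, 0))
  cands <- superpixel_residual_pass(pmd_n, ns0, NULL,
                                    demix_config(corr_thresh = 0.5))
  expect_length(cands, 0)
  # a neuron missing from the initialization appears as one superpixel
  fx <- separated_neuron_movie(n = 5, seed = 47)
  pmd <- decompose_pmd(fx$movie)
  ns <- initialize_temporal(pmd, fx$A[, 1:4])
  ns <- hals_iterate(pmd, ns, n_sweeps = 4)
  bg <- update_background(pmd, ns, ring_radius = 8)
  cands <- superpixel_residual_pass(pmd, ns, bg, demix_config())
  expect_length(cands, 1)
  cover <- sum(cands[[1]]$mask & fx$A[, 5] > 0) / sum(fx$A[, 5] > 0)
  expect_gte(cover, 0.8)
  # with every neuron modeled, the residual is noise: an extreme threshold
  # (and the default one) admits nothing
  ns_full <- hals_iterate(pmd, initialize_temporal(pmd, fx$A), n_sweeps = 4)
  bg_full <- update_background(pmd, ns_full, ring_radius = 8)
  expect_length(superpixel_residual_pass(pmd, ns_full, bg_full,
                                         demix_config(corr_thresh = 0.999)), 0)
})

test_that("multi-pass demixing restores withheld components", {
  fx <- separated_neuron_movie(n = 5, seed = 48)
  pmd <- decompose_pmd(fx$movie)
  res <- run_localnmf(pmd, fx$A[, 1:4])
  expect_equal(ncol(res$neurons$A), 5)
  mt <- match_to_ground_truth(fx$A, fx$C, res$neurons$A, res$neurons$C)
  expect_equal(nrow(mt$pairs), 5)
  expect_true(all(mt$pairs$similarity > 0.9))
  # perfect initialization on a noiseless movie leaves a tiny residual
  z <- noiseless_fixture(seed = 49)
  res2 <- run_localnmf(z$pmd, z$fx$A, config = demix_config(n_passes = 1))
  W <- z$pmd$V - res2$background$Q
  R <- as.matrix(z$pmd$U %*% W) + (z$pmd$means - res2$background$b) -
    res2$neurons$A %*% res2$neurons$C
  UV <- as.matrix(z$pmd$U %*% z$pmd$V) + z$pmd$means
  expect_lt(norm(R, "F") / norm(UV, "F"), 0.05)
  # n_passes = 0 returns the initialization unchanged
  res0 <- run_localnmf(z$pmd, z$fx$A, config = demix_config(n_passes = 0))
  expect_equal(res0$n_passes_run, 0L)
  expect_equal(res0$neurons$A, z$fx$A, ignore_attr = TRUE)
})

test_that("objective decreases across the full demixing loop", {
  fx <- separated_neuron_movie(n = 4, seed = 50)
  pmd <- decompose_pmd(fx$movie)
  res <- run_localnmf(pmd, fx$A)
  # within every HALS block (background fixed) the objective never rises;
  # background updates between blocks may re-base it
  obj <- res$objective
  expect_true(length(obj) >= 2)
  blocks <- split(obj, rep(seq_len(length(obj) / 2), each = 2))
  for (b in blocks) expect_lte(b[2], b[1] * (1 + 1e-9))
})

test_that("demixing never materializes a dense pixels-by-time array", {
  set.seed(51)
  # d * T = 160000 * 500 would be 640 MB dense; the factorized path must
  # stay far below that
  H <- 400; W <- 400; d <- H * W; K <- 25; Tn <- 500; N <- 3
  U <- Matrix::rsparsematrix(d, K, density = 0.01,
                             rand.x = function(n) abs(rnorm(n)))
  pmd <- fake_pmd(U, matrix(rnorm(K * Tn), K, Tn), H, W)
  A <- matrix(0, d, N)
  for (i in seq_len(N)) A[sample.int(d, 150), i] <- runif(150)
  ns <- neuron_set(A, matrix(runif(N * Tn), N, Tn), A > 0)
  gc(reset = TRUE)
  obj <- demix_objective(pmd, ns)
  ns2 <- hals_iterate(pmd, ns, n_sweeps = 1)
  bg <- update_background(pmd, ns2, ring_radius = 3)
  mem <- gc()
  expect_true(is.finite(obj))
  expect_true(all(bg$ring_weights >= 0))
  # peak vector-heap usage ("max used" Mb for Vcells) stays far below the
  # 640 MB a dense d x T copy would need
  mb <- mem["Vcells", ncol(mem)]
  expect_lt(mb, 400)
})
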