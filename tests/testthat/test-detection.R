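# Frame ranking, the baseline blob detector, candidate filtering, and the
# patchwise detection driver.

test_that("frames are ranked by rectified patch brightness", {
  set.seed(31)
  d <- 8 * 8; K <- 3; Tn <- 20
  U <- matrix(abs(rnorm(d * K)), d, K)
  P <- matrix(0, K, Tn)
  P[1, 7] <- 10                      # single transient peaking at frame 7
  sp <- structure(list(P = P, pmd = fake_pmd(U, P, 8, 8)), class = "sparse_movie")
  expect_equal(rank_frames_by_brightness(sp, seq_len(d))[1], 7)
  # all-zero coefficients: stable order by frame index
  sp0 <- structure(list(P = matrix(0, K, Tn), pmd = fake_pmd(U, P, 8, 8)),
                   class = "sparse_movie")
  expect_equal(rank_frames_by_brightness(sp0, seq_len(d)), seq_len(Tn))
  # random instance agrees with the dense brute-force ranking
  P2 <- matrix(rnorm(K * Tn), K, Tn)
  sp2 <- structure(list(P = P2, pmd = fake_pmd(U, P2, 8, 8)), class = "sparse_movie")
  pix <- c(3, 9, 17, 40)
  dense <- pmax(U %*% P2, 0)
  expect_equal(rank_frames_by_brightness(sp2, pix),
               order(apply(dense[pix, ], 2, max), decreasing = TRUE))
})

test_that("the blob detector finds disjoint blobs and applies its filters", {
  yy <- matrix(rep(1:40, times = 40), 40, 40)
  xx <- t(yy)
  blob <- function(cy, cx, r, a) a * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * r^2))
  frame <- blob(10, 10, 3, 1) + blob(30, 28, 3, 0.9)
  dets <- baseline_blob_detector(frame, min_px = 5, max_px = 400, rel_thresh = 0.3)
  expect_length(dets, 2)
  for (dt in dets) {
    pk <- which(frame == max(frame[dt$mask]), arr.ind = TRUE)
    expect_true(dt$mask[pk[1], pk[2]])
  }
  expect_setequal(vapply(dets, function(dt) dt$confidence, numeric(1)),
                  c(1, 0.9))
  # all-zero frame: nothing
  expect_length(baseline_blob_detector(matrix(0, 10, 10)), 0)
  # a blob smaller than min_px is discarded
  small <- matrix(0, 20, 20); small[10, 10] <- 1
  expect_length(baseline_blob_detector(small, min_px = 5), 0)
})

test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # touch diagonally
  lab <- densedemix:::label_components_8(m)
  expect_equal(lab[1, 1], lab[2, 2])
  m[5, 5] <- TRUE
  lab <- densedemix:::label_components_8(m)
  expect_equal(max(lab), 2)
})

test_that("candidate filtering applies the confidence and cosine rules", {
  d <- 100
  params <- detection_params(cmin = 0.7, treal = 0.8, tbin = 0.65)
  cand <- list(image = c(rep(1, 10), rep(0, d - 10)),
               mask = c(rep(TRUE, 10), rep(FALSE, d - 10)),
               confidence = 0.71)
  # confidence just above cmin, empty accepted list: accepted
  expect_true(filter_candidate(cand, NULL, NULL, params)$accept)
  # confidence below cmin: rejected
  cand_lo <- cand; cand_lo$confidence <- 0.69
  expect_equal(filter_candidate(cand_lo, NULL, NULL, params)$reason,
               "confidence")
  # exact duplicate of an accepted footprint: rejected by treal
  acc_img <- matrix(cand$image, d, 1)
  acc_mask <- matrix(as.numeric(cand$mask), d, 1)
  expect_equal(filter_candidate(cand, acc_img, acc_mask, params)$reason,
               "treal")
  # heavy same-frame overlap: rejected
  other <- matrix(as.numeric(cand$mask), d, 1)
  expect_equal(filter_candidate(cand, NULL, NULL, params, other)$reason,
               "frame_overlap")
})

test_that("patchwise detection finds well-separated neurons once each", {
  fx <- separated_neuron_movie(n = 5, seed = 33)
  nn <- estimate_noise_and_normalize(fx$movie)
  pmd <- decompose_pmd(nn$movie)
  sp <- sparsen_movie(pmd, g = 0.9)
  det <- run_patchwise_detection(sp, params = detection_params(n = 40))
  expect_equal(ncol(det$A_init), 5)
  # each accepted footprint's peak lies inside one true footprint
  for (j in seq_len(5)) {
    pk <- which.max(det$A_init[, j])
    expect_true(any(fx$A[pk, ] > 0))
  }
  # pairwise cosine invariants hold exactly
  Ai <- as.matrix(det$A_init)
  M <- det$masks * 1
  nrm <- function(X) sweep(X, 2, sqrt(colSums(X^2)), "/")
  cw <- crossprod(nrm(Ai)); cb <- crossprod(nrm(M))
  diag(cw) <- 0; diag(cb) <- 0
  expect_lt(max(cw), detection_params()$treal)
  expect_lt(max(cb), detection_params()$tbin)
  # determinism: identical inputs give identical output
  det2 <- run_patchwise_detection(sp, params = detection_params(n = 40))
  expect_identical(as.matrix(det$A_init), as.matrix(det2$A_init))
  expect_identical(det$candidates, det2$candidates)
})

test_that("a neuron visible from two patches is accepted only once", {
  # one neuron centered on the boundary between detection patches
  fx <- separated_neuron_movie(n = 1, H = 40, W = 40, Tn = 120, seed = 34)
  nn <- estimate_noise_and_normalize(fx$movie)
  pmd <- decompose_pmd(nn$movie, patch_height = 32, patch_width = 32)
  sp <- sparsen_movie(pmd, g = 0.9)
  det <- run_patchwise_detection(sp, params = detection_params(n = 20))
  expect_equal(ncol(det$A_init), 1)
})

test_that("patch-local candidate lists stay bounded", {
  # the per-patch accepted list is compared against, so its size bounds the
  # quadratic cost per patch; with one neuron per patch it stays tiny
  fx <- separated_neuron_movie(n = 4, seed = 35)
  nn <- estimate_noise_and_normalize(fx$movie)
  pmd <- decompose_pmd(nn$movie)
  sp <- sparsen_movie(pmd, g = 0.9)
  det <- run_patchwise_detection(sp, params = detection_params(n = 30))
  per_patch <- table(det$candidates$patch[det$candidates$reason == "accepted" &
                                            det$candidates$stage == "patch"])
  expect_true(all(per_patch <= 4))
})
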