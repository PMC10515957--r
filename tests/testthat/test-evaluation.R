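# Matching, scoring, the oracle baseline, and demixing-video export.

make_truth <- function(n = 4, d = 200, Tn = 50, seed = 61, overlap = FALSE) {
  set.seed(seed)
  A <- matrix(0, d, n)
  block <- floor(d / n)
  for (i in seq_len(n)) {
    idx <- ((i - 1) * block + 1):(i * block)
    if (overlap && i > 1) idx <- idx - floor(block / 3)
    A[idx, i] <- runif(length(idx), 0.3, 1)
  }
  C <- matrix(abs(rnorm(n * Tn)), n, Tn)
  list(A = A, C = C)
}

test_that("perfect estimates match perfectly and score (1, 0)", {
  tr <- make_truth()
  mt <- match_to_ground_truth(tr$A, tr$C, tr$A, tr$C)
  expect_equal(nrow(mt$pairs), 4)
  expect_true(all(abs(mt$pairs$similarity - 1) < 1e-12))
  expect_length(mt$unmatched_truth, 0)
  expect_length(mt$unmatched_estimates, 0)
  sc <- score_recovery(mt, 4)
  expect_equal(sc$recovery_accuracy, 1.0)
  expect_equal(sc$fpc, 0)
})

test_that("extra estimates become false positives; missing truths score zero", {
  tr <- make_truth()
  set.seed(62)
  extra <- matrix(runif(nrow(tr$A)), ncol = 1) * 0.01
  extra[1:3] <- 1   # a blob unlike any truth footprint
  estA <- cbind(tr$A, extra * 0)
  estA[1:3, 5] <- 1
  estC <- rbind(tr$C, abs(rnorm(ncol(tr$C))))
  mt <- match_to_ground_truth(tr$A, tr$C, estA, estC)
  expect_equal(mt$unmatched_estimates, 5L)
  expect_equal(score_recovery(mt, 4)$fpc, 1)
  # four perfect pairs out of five truths: accuracy 0.8
  mt5 <- match_to_ground_truth(cbind(tr$A, 0 * tr$A[, 1] + c(1, rep(0, 199))),
                               rbind(tr$C, abs(rnorm(50))),
                               tr$A, tr$C)
  expect_equal(score_recovery(mt5, 5)$recovery_accuracy,
               sum(mt5$pairs$similarity) / 5)
  expect_equal(nrow(mt5$pairs), 4)
  expect_lt(score_recovery(mt5, 5)$recovery_accuracy, 0.81)
})

test_that("greedy matching equals exhaustive assignment on small instances", {
  for (seed in 1:5) {
    tr <- make_truth(n = 5, seed = seed)
    # estimates: noisy copies of the truths, in shuffled order
    set.seed(seed + 100)
    perm <- sample(5)
    estA <- tr$A[, perm] + matrix(runif(nrow(tr$A) * 5, 0, 0.05), ncol = 5) *
      (tr$A[, perm] > 0)
    estC <- tr$C[perm, ] + matrix(abs(rnorm(5 * ncol(tr$C), sd = 0.1)), 5)
    mt <- match_to_ground_truth(tr$A, tr$C, estA, estC)
    acc <- score_recovery(mt, 5)$recovery_accuracy
    # exhaustive oracle over all assignments honoring the spatial gate
    spat <- crossprod(sweep(tr$A, 2, sqrt(colSums(tr$A^2)), "/"),
                      sweep(estA, 2, sqrt(colSums(estA^2)), "/"))
    tsim <- outer(seq_len(5), seq_len(5),
                  Vectorize(function(i, j) {
                    densedemix:::cosine_sim(tr$C[i, ], estC[j, ])
                  }))
    best <- 0
    for (p in asplit(all_permutations(5), 1)) {
      s <- sum(ifelse(spat[cbind(1:5, p)] >= 0.5, tsim[cbind(1:5, p)], 0))
      best <- max(best, s / 5)
    }
    expect_equal(acc, best, tolerance = 1e-12)
  }
  # permuting equal-brightness non-overlapping truths leaves the pair set
  tr <- make_truth(n = 4, seed = 7)
  tr$C <- matrix(rep(abs(rnorm(ncol(tr$C))), each = 4), 4)  # equal brightness
  diag_pairs <- match_to_ground_truth(tr$A, tr$C, tr$A, tr$C)$pairs
  perm <- c(3, 1, 4, 2)
  mtp <- match_to_ground_truth(tr$A[, perm], tr$C[perm, ], tr$A, tr$C)
  expect_setequal(paste(perm[mtp$pairs$truth], mtp$pairs$estimate),
                  paste(diag_pairs$truth, diag_pairs$estimate))
})

test_that("accuracy never rises when a matched trace is corrupted", {
  tr <- make_truth(n = 4, seed = 63)
  base <- score_recovery(match_to_ground_truth(tr$A, tr$C, tr$A, tr$C),
                         4)$recovery_accuracy
  set.seed(64)
  for (sd in c(0.1, 0.5, 2)) {
    estC <- tr$C
    estC[2, ] <- pmax(estC[2, ] + rnorm(ncol(estC), sd = sd), 0)
    acc <- score_recovery(match_to_ground_truth(tr$A, tr$C, tr$A, estC),
                          4)$recovery_accuracy
    expect_lte(acc, base + 1e-12)
  }
})

test_that("the oracle recovers traces by nonnegative regression", {
  tr <- make_truth(n = 3, d = 300, Tn = 80, seed = 65)
  Y <- tr$A %*% tr$C
  Co <- oracle_demix(Y, tr$A)
  expect_lt(max(abs(Co - tr$C)), 1e-6)
  # single neuron: rectified closed form
  a <- tr$A[, 1, drop = FALSE]
  Y1 <- a %*% tr$C[1, , drop = FALSE]
  expect_equal(oracle_demix(Y1, a),
               pmax(crossprod(a, Y1) / sum(a^2), 0),
               tolerance = 1e-10, ignore_attr = TRUE)
  # moderate noise: high per-row correlation
  set.seed(66)
  Yn <- Y + matrix(rnorm(length(Y)), nrow(Y))
  Cn <- oracle_demix(Yn, tr$A)
  for (i in 1:3) expect_gt(cor(Cn[i, ], tr$C[i, ]), 0.95)
})

test_that("demixing videos are written with the contracted panels", {
  fx <- separated_neuron_movie(n = 2, H = 32, W = 32, Tn = 60, seed = 67)
  pmd <- decompose_pmd(fx$movie)
  res <- run_localnmf(pmd, fx$A, config = demix_config(n_passes = 1))
  f <- tempfile(fileext = ".tif")
  panels <- export_demix_video(pmd, res, f, frames = 1:5)
  expect_true(file.exists(f))
  expect_false("Ground Truth" %in% panels)
  expect_false("Raw Data" %in% panels)
  # with truth and raw movie the extra panels appear
  truth <- structure(list(A = fx$A, C = fx$C), class = "ground_truth")
  f2 <- tempfile(fileext = ".tif")
  panels2 <- export_demix_video(pmd, res, f2, truth = truth, raw = fx$movie,
                                frames = 1:5)
  expect_true(all(c("Ground Truth", "Raw Data") %in% panels2))
  pages <- tiff::readTIFF(f2, all = TRUE)
  expect_length(pages, 5)
  # a K = 0 decomposition still writes a file of zero panels
  pmd0 <- fake_pmd(matrix(0, 32 * 32, 0), matrix(0, 0, 60), 32, 32)
  res0 <- suppressWarnings(run_localnmf(pmd0, matrix(0, 32 * 32, 0),
                                        config = demix_config(n_passes = 0)))
  f3 <- tempfile(fileext = ".tif")
  export_demix_video(pmd0, res0, f3, frames = 1:3)
  expect_true(file.exists(f3))
})
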