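# Ground-truthed movie simulator: parametric 3D somata are projected
# through a Bessel or two-photon (Gaussian) point-spread function into 2D
# footprints, AR(1) traces are driven by Bernoulli-exponential spiking, and
# signal-scaled Gaussian noise is added. Every draw flows from one seed.

#' Simulation parameters
#'
#' @param height,width FOV size in pixels (default 64 x 64).
#' @param n_frames number of frames T (default 1000).
#' @param k_mean mean neuron count for the Poisson draw used when no target
#'   density is requested (default 15).
#' @param target_rc optional target density Rc (total footprint support
#'   over FOV pixels); when set, footprints are added until the realized
#'   density reaches the target, overriding `k_mean`.
#' @param psf `"bessel"` (unweighted axial sum over the beam length) or
#'   `"gaussian2p"` (Gaussian-weighted axial sum about a random focal
#'   offset).
#' @param axial_length Bessel beam length L in pixels of depth
#'   (default 60).
#' @param sigma_z axial sd of the two-photon PSF in depth pixels
#'   (default 2).
#' @param soma_radius_range soma radius range in pixels, drawn uniformly
#'   (default c(4, 7): supports of roughly 50-150 px in a 64 x 64 FOV).
#' @param scale_range brightness scaling factors, drawn log-uniformly
#'   (default c(3, 10): clearly supra-noise transients after unit-noise
#'   normalization, the high-SNR regime).
#' @param spike_rate spike probability per neuron per frame (default 0.01,
#'   i.e. ~10 transients over 1000 frames).
#' @param g AR(1) calcium decay coefficient (default 0.9).
#' @param sigma0 noise floor standard deviation (default 1).
#' @param alpha signal-proportional noise variance gain: the noise variance
#'   at a pixel and frame is `sigma0^2 + alpha * signal` (default 0.5).
#' @param label_percentile percentile p for detection labels, in
#'   `[0, 100]`; values in `[40, 80]` are the recommended band
#'   (default 60).
#' @param smooth_sigma optical blur applied to footprints, in pixels
#'   (default 0.5).
#' @param seed integer seed from which all randomness flows (default 1).
#' @return a `sim_params` list.
#' @export
sim_params <- function(height = 64, width = 64, n_frames = 1000,
                       k_mean = 15, target_rc = NULL,
                       psf = c("bessel", "gaussian2p"),
                       axial_length = 60, sigma_z = 2,
                       soma_radius_range = c(4, 7),
                       scale_range = c(3, 10), spike_rate = 0.01,
                       g = 0.9, sigma0 = 1, alpha = 0.5,
                       label_percentile = 60, smooth_sigma = 0.5,
                       seed = 1) {
  psf <- match.arg(psf)
  stopifnot(height > 0, width > 0, n_frames >= 2, k_mean > 0,
            axial_length > 0, sigma_z > 0, all(soma_radius_range > 0),
            all(scale_range > 0), spike_rate >= 0, g >= 0, g < 1,
            sigma0 >= 0, alpha >= 0,
            label_percentile >= 0, label_percentile <= 100)
  if (!is.null(target_rc)) stopifnot(target_rc > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), k_mean = k_mean,
                 target_rc = target_rc, psf = psf,
                 axial_length = axial_length, sigma_z = sigma_z,
                 soma_radius_range = soma_radius_range,
                 scale_range = scale_range, spike_rate = spike_rate,
                 g = g, sigma0 = sigma0, alpha = alpha,
                 label_percentile = label_percentile,
                 smooth_sigma = smooth_sigma, seed = seed),
            class = "sim_params")
}

# Project one random soma through the PSF onto a local image. Returns a
# peak-normalized footprint image (support = values above 5% of peak).
# `axes` (ellipsoid semi-axes) and `z0` (two-photon focal offset) may be
# forced; by default they are drawn from the parameter distributions.
project_soma <- function(params, axes = NULL, z0 = NULL) {
  ax <- if (is.null(axes)) {
    r <- stats::runif(1, params$soma_radius_range[1], params$soma_radius_range[2])
    r * stats::runif(3, 0.85, 1.15)   # mildly anisotropic ellipsoid
  } else axes
  ext <- ceiling(max(ax[1:2]) + 3 * params$smooth_sigma + 1)
  n <- 2L * ext + 1L
  yy <- matrix(rep(-ext:ext, n), n, n)
  xx <- t(yy)
  rho2 <- (yy / ax[1])^2 + (xx / ax[2])^2
  if (params$psf == "bessel") {
    # unweighted sum over z across the beam length: for a full ellipsoid
    # inside the beam this is the chord length 2*az*sqrt(1 - rho^2)
    img <- 2 * ax[3] * sqrt(pmax(1 - rho2, 0))
  } else {
    # Gaussian-weighted axial sum about a random focal offset z0
    if (is.null(z0)) z0 <- stats::rnorm(1, 0, ax[3] / 2)
    zs <- seq(-ax[3], ax[3], length.out = 25)
    wz <- exp(-(zs - z0)^2 / (2 * params$sigma_z^2))
    img <- matrix(0, n, n)
    for (i in seq_along(zs)) {
      inside <- rho2 <= 1 - (zs[i] / ax[3])^2
      img <- img + wz[i] * inside
    }
  }
  img <- gaussian_blur(img, params$smooth_sigma)
  pk <- max(img)
  if (pk <= 0) return(NULL)
  img <- img / pk
  img[img < 0.05] <- 0
  img
}

#' Generate simulated neuron footprints
#'
#' Each footprint is a random 3D soma ellipsoid projected through the
#' configured point-spread function (Bessel: unweighted sum over depth;
#' two-photon: Gaussian-weighted sum about a random focal offset), blurred,
#' thresholded at 5% of peak to define the support, peak-normalized to 1,
#' and placed at a uniform-random position fully inside the FOV.
#'
#' @param params a [sim_params]. Uses the current RNG stream (callers that
#'   need reproducibility should seed; [simulate_ground_truth] does).
#' @param n number of footprints.
#' @return sparse `d x n` nonnegative matrix (row-major unrolled pixels).
#' @export
generate_footprints <- function(params, n) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  H <- params$height; W <- params$width; d <- H * W
  ii <- list(); jj <- list(); xx <- list()
  for (k in seq_len(n)) {
    img <- NULL
    for (try in 1:10) {
      img <- project_soma(params)
      if (!is.null(img) && any(img > 0)) break
    }
    if (is.null(img)) stop("failed to generate a footprint with nonempty support")
    nh <- nrow(img); nw <- ncol(img)
    y0 <- sample.int(H - nh + 1L, 1)
    x0 <- sample.int(W - nw + 1L, 1)
    sel <- which(img > 0)
    ry <- ((sel - 1L) %% nh) + y0
    rx <- ((sel - 1L) %/% nh) + x0
    ii[[k]] <- (ry - 1L) * W + rx
    jj[[k]] <- rep.int(k, length(sel))
    xx[[k]] <- img[sel]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(d, n))
}

#' Sample AR(1) calcium traces driven by Bernoulli-exponential spikes
#'
#' Spikes occur independently per frame with probability `spike_rate` and
#' exponential(1) amplitudes; calcium is the AR(1) filtering of the spike
#' train with coefficient `g`; each row is multiplied by a brightness
#' scale drawn log-uniformly from `scale_range`.
#'
#' @param params a [sim_params].
#' @param n number of neurons.
#' @return list with `C` (`n x T` nonnegative), `spikes` (`n x T`, includes
#'   the row scaling), and `scales` (length n).
#' @export
sample_traces <- function(params, n) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  Tn <- params$n_frames
  S <- matrix(stats::rbinom(n * Tn, 1, params$spike_rate) *
                stats::rexp(n * Tn), n, Tn)
  scales <- exp(stats::runif(n, log(params$scale_range[1]),
                             log(params$scale_range[2])))
  S <- S * scales
  C <- t(apply(S, 1, function(s) {
    as.numeric(stats::filter(s, params$g, method = "recursive"))
  }))
  if (n == 1) C <- matrix(C, 1, Tn)
  list(C = C, spikes = S, scales = scales)
}

#' Synthesize a noisy movie from footprints and traces
#'
#' `Y = A C + E` with independent Gaussian noise whose variance scales
#' with the signal: `Var(E[i, t]) = sigma0^2 + alpha * (A C)[i, t]`.
#'
#' @param A `d x n` footprint matrix (sparse or dense).
#' @param C `n x T` trace matrix.
#' @param params a [sim_params] (supplies `sigma0`, `alpha`, FOV size).
#' @return a [movie].
#' @export
synthesize_movie <- function(A, C, params) {
  stopifnot(inherits(params, "sim_params"))
  AC <- as.matrix(A %*% C)
  sdm <- sqrt(params$sigma0^2 + params$alpha * pmax(AC, 0))
  Y <- AC + matrix(stats::rnorm(length(AC)), nrow(AC), ncol(AC)) * sdm
  movie(Y, params$height, params$width)
}

#' Threshold deconvolved traces into per-frame detection labels
#'
#' Each trace row is deconvolved with the naive AR(1) operator
#' (`s_t = c_t - g c_{t-1}`, rectified at zero); the row's threshold is the
#' `p`-th percentile of its positive deconvolved values, and activity below
#' the threshold is zeroed. A neuron counts as a positive instance in every
#' frame where its thresholded trace is nonzero.
#'
#' @param C `n x T` trace matrix.
#' @param g AR(1) coefficient.
#' @param p percentile in `[0, 100]`.
#' @return list with `C_prime` (`n x T` thresholded deconvolved traces) and
#'   `positives` (list of length T: neuron indices active per frame).
#' @export
make_detection_labels <- function(C, g, p) {
  if (p < 0 || p > 100) stop("label percentile p must lie in [0, 100]")
  C <- as.matrix(C)
  Tn <- ncol(C)
  S <- C
  if (Tn >= 2) S[, 2:Tn] <- C[, 2:Tn] - g * C[, 1:(Tn - 1)]
  S[S < 0] <- 0
  Cp <- matrix(0, nrow(C), Tn)
  for (i in seq_len(nrow(C))) {
    pos <- S[i, S[i, ] > 0]
    if (length(pos) == 0) next
    th <- stats::quantile(pos, p / 100, names = FALSE)
    keep <- S[i, ] >= th & S[i, ] > 0
    Cp[i, keep] <- S[i, keep]
  }
  positives <- lapply(seq_len(Tn), function(t) which(Cp[, t] > 0))
  list(C_prime = Cp, positives = positives)
}

#' Simulate a ground-truthed movie
#'
#' Draws footprints, traces, and noise from a single seed and packages the
#' movie together with its ground truth. The neuron count is Poisson
#' (`k_mean`) unless `target_rc` is set, in which case footprints are
#' accumulated until the realized density `Rc = sum_i |supp(a_i)| / d`
#' reaches the target.
#'
#' @param params a [sim_params].
#' @return list with `movie` and `truth` (a `ground_truth`: `A`, `C`,
#'   `spikes`, `C_prime`, `positives`, `Rc`, `seed`).
#' @export
simulate_ground_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_local_seed(params$seed, {
    d <- params$height * params$width
    if (!is.null(params$target_rc)) {
      cols <- list()
      rc <- 0
      while (rc < params$target_rc) {
        a <- generate_footprints(params, 1)
        cols[[length(cols) + 1L]] <- a
        rc <- rc + sum(a > 0) / d
      }
      A <- do.call(cbind, cols)
    } else {
      k <- max(1L, stats::rpois(1, params$k_mean))
      A <- generate_footprints(params, k)
    }
    n <- ncol(A)
    tr <- sample_traces(params, n)
    m <- synthesize_movie(A, tr$C, params)
    lab <- make_detection_labels(tr$C, params$g, params$label_percentile)
    truth <- structure(
      list(A = A, C = tr$C, spikes = tr$spikes, C_prime = lab$C_prime,
           positives = lab$positives,
           Rc = sum(Matrix::colSums(A > 0)) / d, seed = params$seed),
      class = "ground_truth")
    list(movie = m, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d neurons, T = %d, Rc = %.2f\n",
              ncol(x$A), ncol(x$C), x$Rc))
  invisible(x)
}

#' Generate detector training examples from simulated movies
#'
#' For each simulated video the full front half of the pipeline is run
#' (noise normalization, compression, naive sparsening, projection), and
#' the `n_top` brightest frames of each detection patch are emitted as
#' images paired with the masks of the label-positive neurons intersecting
#' that patch — the supervision pairs an instance-segmentation detector
#' trains on.
#'
#' @param params a [sim_params]; video v uses seed `params$seed + v - 1`.
#' @param n_videos number of simulated videos.
#' @param n_top brightest frames per patch to emit (default 5).
#' @param patch_size,patch_pad detection patch geometry (defaults 20, 8).
#' @return list of examples, each with `image` (padded patch frame),
#'   `masks` (list of logical full-FOV masks of positive neurons
#'   intersecting the patch), `frame`, `patch`, `video`.
#' @export
generate_training_examples <- function(params, n_videos, n_top = 5,
                                       patch_size = 20, patch_pad = 8) {
  stopifnot(inherits(params, "sim_params"), n_videos >= 1)
  out <- list()
  for (v in seq_len(n_videos)) {
    pv <- params
    pv$seed <- params$seed + v - 1L
    sim <- simulate_ground_truth(pv)
    nn <- estimate_noise_and_normalize(sim$movie)
    pmd <- decompose_pmd(nn$movie)
    if (pmd$K == 0) next
    sp <- deconvolve_naive_on_V(pmd, pv$g)
    H <- pv$height; W <- pv$width
    ys <- detection_patch_starts(H, min(patch_size, H))
    xs <- detection_patch_starts(W, min(patch_size, W))
    supp <- as.matrix(sim$truth$A > 0)
    patch_id <- 0L
    for (y0 in ys) for (x0 in xs) {
      patch_id <- patch_id + 1L
      yy <- y0:min(y0 + patch_size - 1L, H)
      xx <- x0:min(x0 + patch_size - 1L, W)
      core_pix <- as.integer(outer(xx, (yy - 1L) * W, `+`))
      yyp <- max(1L, y0 - patch_pad):min(H, max(yy) + patch_pad)
      xxp <- max(1L, x0 - patch_pad):min(W, max(xx) + patch_pad)
      pad_pix <- as.integer(outer(xxp, (yyp - 1L) * W, `+`))
      ord <- rank_frames_by_brightness(sp, core_pix)
      top <- ord[seq_len(min(n_top, length(ord)))]
      Xf <- render_sparse_frames(sp, pad_pix, top)
      in_patch <- which(colSums(supp[pad_pix, , drop = FALSE]) > 0)
      for (fi in seq_along(top)) {
        t <- top[fi]
        act <- intersect(sim$truth$positives[[t]], in_patch)
        masks <- lapply(act, function(i) supp[, i])
        out[[length(out) + 1L]] <- list(
          image = matrix(Xf[, fi], length(yyp), length(xxp), byrow = TRUE),
          masks = masks, frame = t, patch = patch_id, video = v)
      }
    }
  }
  out
}
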