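#' Run the full demixing pipeline on a movie
#'
#' Chains the stages end to end: optional rigid registration, per-pixel
#' noise normalization, patchwise low-rank compression, temporal
#' sparsening (naive AR(1) deconvolution on the temporal basis by
#' default), patchwise footprint detection, and multi-pass constrained NMF
#' demixing.
#'
#' @param m a [movie].
#' @param register run rigid registration first (default FALSE; simulated
#'   or pre-registered movies do not need it).
#' @param max_shift registration bound in pixels (when `register = TRUE`).
#' @param patch_height,patch_width,overlap,rank_margin,max_rank compression
#'   parameters (see [decompose_pmd]).
#' @param sparsen_method `"naive"` or `"oasis"` (see [sparsen_movie]).
#' @param g AR(1) coefficient; `NULL` estimates it from the data.
#' @param det a [detector] (default [blob_detector]).
#' @param det_params a [detection_params].
#' @param config a [demix_config].
#' @param seed seed for the randomized SVD range finder.
#' @return list with `pmd`, `sparse`, `detection`, `result` (a
#'   `demix_result`), `noise`, and `g`.
#' @export
demix_pipeline <- function(m, register = FALSE, max_shift = 8,
                           patch_height = 32, patch_width = 32,
                           overlap = 0.5, rank_margin = 0.05, max_rank = 50,
                           sparsen_method = c("naive", "oasis"), g = NULL,
                           det = blob_detector(),
                           det_params = detection_params(),
                           config = demix_config(), seed = 0) {
  stopifnot(inherits(m, "movie"))
  sparsen_method <- match.arg(sparsen_method)
  if (register) {
    m <- rigid_register(m, max_shift = max_shift)$registered
  }
  nn <- estimate_noise_and_normalize(m)
  pmd <- decompose_pmd(nn$movie, patch_height = patch_height,
                       patch_width = patch_width, overlap = overlap,
                       rank_margin = rank_margin, max_rank = max_rank,
                       seed = seed)
  if (pmd$K == 0) stop("compression retained no components; nothing to demix")
  if (is.null(g)) g <- estimate_ar_coefficient(pmd)
  sparse <- sparsen_movie(pmd, method = sparsen_method, g = g)
  detection <- run_patchwise_detection(sparse, det = det, params = det_params)
  result <- run_localnmf(pmd, detection$A_init, detection$masks,
                         config = config)
  list(pmd = pmd, sparse = sparse, detection = detection, result = result,
       noise = nn$noise, g = g)
}
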