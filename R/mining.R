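# Candidate proposal and hard-negative (false-positive) mining. The
# shipped proposer is a multi-scale Laplacian-of-Gaussian blob detector on
# inverted intensities: any detector honouring the candidate contract
# (center, score, scale) can stand in for it.

#' Candidate proposer configuration
#'
#' @param scales blob radii to probe, voxels; each radius r is probed at
#'   Gaussian scale `sigma = r / sqrt(3)` (the scale at which a solid 3D
#'   blob of radius r maximises the normalised LoG response).
#' @param response_threshold minimum scale-normalised response; candidate
#'   local maxima below it are discarded. Volumes are expected
#'   standardised, so the threshold is in units of intensity SD.
#' @param max_candidates per-scan cap, strongest first.
#' @param match_radius Chebyshev distance (voxels) within which a
#'   candidate claims a ground-truth microbleed; the default 5 is half
#'   the 11-voxel patch edge, so a true positive's centred patch contains
#'   the lesion centre.
#' @return An object of class `proposer_config`.
#' @export
proposer_config <- function(scales = c(1, 2, 3), response_threshold = 1,
                            max_candidates = 100L, match_radius = 5L) {
  if (!length(scales) || any(scales <= 0))
    stop("`scales` must be a nonempty positive vector")
  if (match_radius < 1) stop("`match_radius` must be >= 1")
  structure(list(scales = as.numeric(scales),
                 response_threshold = response_threshold,
                 max_candidates = as.integer(max_candidates),
                 match_radius = as.integer(match_radius)),
            class = "proposer_config")
}

#' Propose microbleed candidates on a whole volume
#'
#' Computes the scale-normalised Laplacian-of-Gaussian response of the
#' inverted (hypointensity) image at each configured radius, takes the
#' voxelwise maximum across scales, and returns local maxima (26-connected
#' neighbourhood) above the response threshold, strongest first, after
#' non-maximum suppression at Chebyshev radius `max(scales)` and capped at
#' `max_candidates`.
#'
#' @param volume a `cmb_volume`, expected standardised
#'   (see [normalize_volume()]).
#' @param config a [proposer_config()].
#' @return A data.frame with columns `x,y,z` (0-based voxel centre),
#'   `score`, `scale` (best-responding radius); zero rows when nothing
#'   exceeds the threshold.
#' @export
propose_candidates <- function(volume, config = proposer_config()) {
  stopifnot(inherits(volume, "cmb_volume"))
  inv <- -volume$data
  best <- array(-Inf, dim = dim(inv))
  best_scale <- array(NA_real_, dim = dim(inv))
  for (r in config$scales) {
    sigma <- r / sqrt(3)
    resp <- -sigma^2 * laplacian3d(gauss_smooth3d(inv, sigma))
    upd <- resp > best
    best[upd] <- resp[upd]
    best_scale[upd] <- r
  }
  # local maxima over the 26-neighbourhood
  is_max <- array(TRUE, dim = dim(best))
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift_axis(shift_axis(shift_axis(best, dx, 1L), dy, 2L), dz, 3L)
    is_max <- is_max & best >= nb
  }
  # exclude a border band where padded smoothing biases the response
  border <- ceiling(2 * max(config$scales))
  d <- dim(best)
  if (all(d > 2 * border)) {
    mask <- array(FALSE, dim = d)
    mask[(border + 1):(d[1] - border), (border + 1):(d[2] - border),
         (border + 1):(d[3] - border)] <- TRUE
    is_max <- is_max & mask
  }
  keep <- which(is_max & best > config$response_threshold)
  if (!length(keep))
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      score = numeric(0), scale = numeric(0)))
  idx0 <- keep - 1L
  cand <- data.frame(x = idx0 %% d[1],
                     y = (idx0 %/% d[1]) %% d[2],
                     z = idx0 %/% (d[1] * d[2]),
                     score = best[keep], scale = best_scale[keep])
  cand <- cand[order(-cand$score), , drop = FALSE]
  # greedy non-maximum suppression
  sup_r <- max(config$scales)
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(sel)) {
      prev <- cand[sel, , drop = FALSE]
      if (any(pmax(abs(prev$x - cand$x[i]), abs(prev$y - cand$y[i]),
                   abs(prev$z - cand$z[i])) <= sup_r)) next
    }
    sel[i] <- TRUE
    if (sum(sel) >= config$max_candidates) break
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition candidates into true and false positives
#'
#' A candidate is a true positive iff an unclaimed microbleed record lies
#' within Chebyshev distance `match_radius` of its centre. Matching is
#' greedy in descending score order and one-to-one: each record claims at
#' most one candidate; among several records in range the nearest wins
#' (ties by record order). Remaining candidates are false positives; with
#' no records (a normal scan) every candidate is a false positive.
#'
#' @param candidates data.frame from [propose_candidates()].
#' @param records lesion records data.frame (columns `x,y,z,kind`); only
#'   `kind == "cmb"` rows count as targets. May be empty.
#' @param match_radius Chebyshev matching radius, voxels.
#' @return A list with data.frames `tp` and `fp` (candidate rows, `tp`
#'   augmented with the matched record index).
#' @export
match_candidates <- function(candidates, records, match_radius = 5L) {
  cc <- if (!is.null(records) && nrow(records))
    records[records$kind == "cmb", , drop = FALSE] else records
  ord <- order(-candidates$score)
  claimed <- if (is.null(cc)) logical(0) else logical(nrow(cc))
  is_tp <- logical(nrow(candidates))
  match_idx <- rep(NA_integer_, nrow(candidates))
  for (i in ord) {
    if (is.null(cc) || !nrow(cc)) break
    dch <- pmax(abs(cc$x - candidates$x[i]), abs(cc$y - candidates$y[i]),
                abs(cc$z - candidates$z[i]))
    ok <- which(!claimed & dch <= match_radius)
    if (length(ok)) {
      j <- ok[which.min(dch[ok])]
      claimed[j] <- TRUE
      is_tp[i] <- TRUE
      match_idx[i] <- j
    }
  }
  tp <- candidates[is_tp, , drop = FALSE]
  tp$record <- match_idx[is_tp]
  list(tp = tp, fp = candidates[!is_tp, , drop = FALSE])
}

#' Harvest false-positive patches as hard negatives
#'
#' Extracts one window per false-positive candidate, centred on the
#' candidate (shifted inward at volume boundaries), labelled `non_cmb`
#' with provenance `mined_fp`.
#'
#' @param volume a `cmb_volume` (same intensity space as the training
#'   patches, i.e. standardised).
#' @param fp_list data.frame of false positives (columns `x,y,z`).
#' @param spec a [patch_spec()].
#' @param scan_id scan identifier recorded in the patch metadata.
#' @return A `patch_set`.
#' @export
harvest_fp_patches <- function(volume, fp_list, spec = patch_spec(),
                               scan_id = "scan") {
  e <- spec$edge
  if (is.null(fp_list) || !nrow(fp_list)) return(empty_patch_set(e))
  d <- dim(volume$data)
  half <- (e - 1L) %/% 2L
  xmat <- matrix(0, nrow = e^3, ncol = nrow(fp_list))
  ctr <- matrix(0L, nrow = nrow(fp_list), ncol = 3)
  for (i in seq_len(nrow(fp_list))) {
    o <- centered_origin(c(fp_list$x[i], fp_list$y[i], fp_list$z[i]), e, d)
    xmat[, i] <- as.vector(extract_block(volume$data, o, e))
    ctr[i, ] <- o + half
  }
  meta <- data.frame(scan_id = scan_id, cx = ctr[, 1], cy = ctr[, 2],
                     cz = ctr[, 3], label = "non_cmb",
                     provenance = "mined_fp", stringsAsFactors = FALSE)
  dup <- duplicated(meta[, c("scan_id", "cx", "cy", "cz")])
  patch_set(xmat[, !dup, drop = FALSE], meta[!dup, , drop = FALSE], e)
}

#' False positives per scan
#'
#' @param n_fp total false positives.
#' @param n_scans number of scans (>= 1).
#' @return The exact quotient (summaries print it to 1 decimal).
#' @export
per_scan_fp_rate <- function(n_fp, n_scans) {
  if (n_scans < 1) stop("`n_scans` must be >= 1")
  n_fp / n_scans
}

#' False positives per slice
#'
#' @param n_fp total false positives.
#' @param n_slices number of 2D slices (>= 1).
#' @return The exact quotient.
#' @export
per_slice_fp_rate <- function(n_fp, n_slices) {
  if (n_slices < 1) stop("`n_slices` must be >= 1")
  n_fp / n_slices
}
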