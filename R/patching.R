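# Labelled 3D patch extraction: non-overlapping sliding-window tiling,
# lesion-centred windows, undersampling, and the four training-set
# assembly strategies for class-imbalance handling.

#' Patch extraction geometry
#'
#' @param edge cubic patch edge in voxels; odd and >= 3 (default 11).
#' @param stride tiling stride in voxels (default `edge`: non-overlapping).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(edge = 11L, stride = edge) {
  edge <- as.integer(edge); stride <- as.integer(stride)
  if (edge < 3L || edge %% 2L == 0L) stop("`edge` must be odd and >= 3")
  if (stride < 1L) stop("`stride` must be >= 1")
  structure(list(edge = edge, stride = stride), class = "patch_spec")
}

#' Construct a patch set
#'
#' A `patch_set` holds patch intensity blocks as the columns of an
#' `edge^3 x n` matrix plus a metadata row per patch: `scan_id`, the patch
#' centre voxel (0-based), `label` in `{cmb, non_cmb}` and `provenance` in
#' `{sliding, centered, mined_fp, augmented}`.
#'
#' @param x `edge^3 x n` numeric matrix, one column per patch.
#' @param meta data.frame with columns `scan_id,cx,cy,cz,label,provenance`.
#' @param edge patch edge length.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(x, meta, edge) {
  edge <- as.integer(edge)
  if (!is.matrix(x) || nrow(x) != edge^3)
    stop("`x` must be an edge^3 x n matrix")
  if (nrow(meta) != ncol(x)) stop("metadata rows must match patch count")
  need <- c("scan_id", "cx", "cy", "cz", "label", "provenance")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ","))
  if (!all(meta$label %in% c("cmb", "non_cmb")))
    stop("labels must be 'cmb' or 'non_cmb'")
  if (!all(meta$provenance %in% c("sliding", "centered", "mined_fp",
                                  "augmented")))
    stop("unknown provenance value")
  chk <- meta$provenance != "augmented"  # stochastic copies may repeat keys
  key <- paste(meta$scan_id, meta$cx, meta$cy, meta$cz,
               meta$provenance)[chk]
  if (anyDuplicated(key))
    stop("duplicate (scan_id, center, provenance) keys in patch set")
  structure(list(x = x, meta = meta, edge = edge), class = "patch_set")
}

#' An empty patch set
#' @param edge patch edge length.
#' @return A `patch_set` with zero patches.
#' @export
empty_patch_set <- function(edge) {
  patch_set(matrix(numeric(0), nrow = edge^3, ncol = 0),
            data.frame(scan_id = character(0), cx = integer(0),
                       cy = integer(0), cz = integer(0),
                       label = character(0), provenance = character(0),
                       stringsAsFactors = FALSE),
            edge)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d^3 voxels (%d cmb, %d non_cmb)\n",
              n_patches(x), x$edge, sum(x$meta$label == "cmb"),
              sum(x$meta$label == "non_cmb")))
  if (n_patches(x)) print(table(x$meta$provenance))
  invisible(x)
}

#' Number of patches in a set
#' @param ps a `patch_set`.
#' @return Integer count.
#' @export
n_patches <- function(ps) ncol(ps$x)

#' Class counts of a patch set
#' @param ps a `patch_set`.
#' @return Named integer vector with elements `cmb` and `non_cmb`.
#' @export
class_counts <- function(ps) {
  c(cmb = sum(ps$meta$label == "cmb"),
    non_cmb = sum(ps$meta$label == "non_cmb"))
}

#' Subset a patch set
#' @param ps a `patch_set`.
#' @param i index vector over patches.
#' @return A `patch_set`.
#' @export
subset_patches <- function(ps, i) {
  patch_set(ps$x[, i, drop = FALSE], ps$meta[i, , drop = FALSE], ps$edge)
}

#' Combine patch sets
#' @param ... `patch_set` objects with equal edge.
#' @return A `patch_set`.
#' @export
bind_patches <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  if (!length(sets)) stop("no patch sets given")
  edges <- unique(vapply(sets, function(s) s$edge, 1L))
  if (length(edges) != 1) stop("patch sets have differing edge lengths")
  nonempty <- sets[vapply(sets, n_patches, 1L) > 0]
  if (!length(nonempty)) return(empty_patch_set(edges))
  patch_set(do.call(cbind, lapply(nonempty, function(s) s$x)),
            do.call(rbind, lapply(nonempty, function(s) s$meta)),
            edges)
}

extract_block <- function(arr, origin, edge) {
  # origin is the 0-based corner; block is [origin, origin+edge-1]^3
  arr[origin[1] + seq_len(edge), origin[2] + seq_len(edge),
      origin[3] + seq_len(edge)]
}

cmb_centers <- function(lvol) {
  r <- lvol$records
  r[r$kind == "cmb", c("x", "y", "z", "radius"), drop = FALSE]
}

#' Extract patches by non-overlapping sliding window
#'
#' Tiles the volume on a `stride` grid starting at the origin, dropping
#' partial windows at the far edges. A patch is labelled `cmb` iff at
#' least one microbleed record centre lies inside its voxel extent.
#'
#' @param lvol a `labeled_volume`.
#' @param spec a [patch_spec()].
#' @param exclude_cmb_margin if `TRUE`, tiles whose extent intersects any
#'   microbleed sphere (centre +/- radius, Chebyshev) but are labelled
#'   `non_cmb` are dropped, keeping the non-CMB pool free of label noise
#'   when used alongside lesion-centred positives.
#' @return A `patch_set` with provenance `sliding`.
#' @export
extract_sliding <- function(lvol, spec = patch_spec(),
                            exclude_cmb_margin = FALSE) {
  stopifnot(inherits(lvol, "labeled_volume"))
  d <- dim(lvol$volume$data)
  e <- spec$edge
  if (any(d < e)) stop("patch edge ", e, " exceeds a volume axis")
  origins <- lapply(1:3, function(a) seq(0L, d[a] - e, by = spec$stride))
  grid <- expand.grid(x = origins[[1]], y = origins[[2]], z = origins[[3]])
  cc <- cmb_centers(lvol)
  n <- nrow(grid)
  xmat <- matrix(0, nrow = e^3, ncol = n)
  label <- character(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    o <- as.integer(grid[i, ])
    xmat[, i] <- as.vector(extract_block(lvol$volume$data, o, e))
    inside <- nrow(cc) > 0 &&
      any(cc$x >= o[1] & cc$x <= o[1] + e - 1 &
          cc$y >= o[2] & cc$y <= o[2] + e - 1 &
          cc$z >= o[3] & cc$z <= o[3] + e - 1)
    label[i] <- if (inside) "cmb" else "non_cmb"
    if (exclude_cmb_margin && !inside && nrow(cc) > 0) {
      # annotations loaded from CSV carry no radius; assume the largest
      # default lesion radius for the exclusion margin
      r <- ifelse(is.na(cc$radius), 3, cc$radius)
      touches <- any(cc$x + r >= o[1] & cc$x - r <= o[1] + e - 1 &
                     cc$y + r >= o[2] & cc$y - r <= o[2] + e - 1 &
                     cc$z + r >= o[3] & cc$z - r <= o[3] + e - 1)
      if (touches) keep[i] <- FALSE
    }
  }
  half <- (e - 1L) %/% 2L
  meta <- data.frame(scan_id = lvol$scan_id,
                     cx = grid$x + half, cy = grid$y + half,
                     cz = grid$z + half, label = label,
                     provenance = "sliding", stringsAsFactors = FALSE)
  patch_set(xmat[, keep, drop = FALSE], meta[keep, , drop = FALSE], e)
}

centered_origin <- function(center, edge, d) {
  half <- (edge - 1L) %/% 2L
  pmin(pmax(as.integer(center) - half, 0L), d - edge)
}

#' Extract one lesion-centred patch per microbleed
#'
#' Windows are centred on each microbleed record; at volume boundaries the
#' window is shifted inward so the block stays inside the volume (no
#' padding), in which case the record is off-centre but still contained.
#'
#' @param lvol a `labeled_volume`.
#' @param spec a [patch_spec()].
#' @return A `patch_set` with provenance `centered`, all labelled `cmb`.
#' @export
extract_centered <- function(lvol, spec = patch_spec()) {
  stopifnot(inherits(lvol, "labeled_volume"))
  d <- dim(lvol$volume$data)
  e <- spec$edge
  if (any(d < e)) stop("patch edge ", e, " exceeds a volume axis")
  cc <- cmb_centers(lvol)
  if (!nrow(cc)) return(empty_patch_set(e))
  half <- (e - 1L) %/% 2L
  xmat <- matrix(0, nrow = e^3, ncol = nrow(cc))
  ctr <- matrix(0L, nrow = nrow(cc), ncol = 3)
  for (i in seq_len(nrow(cc))) {
    o <- centered_origin(c(cc$x[i], cc$y[i], cc$z[i]), e, d)
    xmat[, i] <- as.vector(extract_block(lvol$volume$data, o, e))
    ctr[i, ] <- o + half
  }
  meta <- data.frame(scan_id = lvol$scan_id, cx = ctr[, 1], cy = ctr[, 2],
                     cz = ctr[, 3], label = "cmb", provenance = "centered",
                     stringsAsFactors = FALSE)
  # two records can share a window centre after boundary shifting
  dup <- duplicated(meta[, c("scan_id", "cx", "cy", "cz")])
  patch_set(xmat[, !dup, drop = FALSE], meta[!dup, , drop = FALSE], e)
}

#' Undersample the non-CMB class
#'
#' Keeps every `cmb` patch and a uniform random subset of `non_cmb`
#' patches of size `min(pool, round(ratio * n_cmb))`.
#'
#' @param ps a `patch_set` containing both classes.
#' @param ratio non-CMB patches retained per CMB patch.
#' @param seed RNG seed.
#' @return A `patch_set`.
#' @export
undersample <- function(ps, ratio = 1, seed = 1L) {
  cc <- class_counts(ps)
  if (cc[["cmb"]] == 0) stop("undersample requires at least one cmb patch")
  if (ratio <= 0) stop("`ratio` must be positive")
  pos <- which(ps$meta$label == "cmb")
  neg <- which(ps$meta$label == "non_cmb")
  want <- round(ratio * length(pos))
  if (want >= length(neg)) {
    if (want > length(neg))
      warning("undersample ratio exhausts the non-CMB pool (",
              length(neg), " available, ", want, " requested); keeping all")
    keep <- neg
  } else {
    keep <- with_seed(seed, sample(neg, want))
  }
  subset_patches(ps, sort(c(pos, keep)))
}

#' Training-set assembly strategy
#'
#' @param strategy one of `"A"` (CMB + undersampled non-CMB), `"B"`
#'   (CMB + all non-CMB), `"C"` (CMB + all non-CMB + mined false
#'   positives), `"D"` (CMB + mined false positives only).
#' @param undersample_ratio non-CMB per CMB for strategy A.
#' @param seed RNG seed used by strategy A's undersampling.
#' @return An object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("A", "B", "C", "D"),
                            undersample_ratio = 1, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "A" && undersample_ratio <= 0)
    stop("strategy A needs a positive undersample_ratio")
  structure(list(strategy = strategy,
                 undersample_ratio = undersample_ratio,
                 seed = as.integer(seed)),
            class = "strategy_config")
}

#' Assemble a training set under one imbalance strategy
#'
#' @param config a [strategy_config()].
#' @param cmb `patch_set` of CMB-labelled patches.
#' @param non_cmb `patch_set` of sliding-window non-CMB patches.
#' @param mined_fp `patch_set` of detector false positives (hard
#'   negatives); required for strategies C and D; any labels are forced
#'   to `non_cmb`.
#' @return A `patch_set`.
#' @export
assemble_training_set <- function(config, cmb, non_cmb,
                                  mined_fp = NULL) {
  stopifnot(inherits(config, "strategy_config"))
  if (config$strategy %in% c("C", "D") &&
      (is.null(mined_fp) || n_patches(mined_fp) == 0))
    stop("strategy ", config$strategy,
         " requires a nonempty mined_fp patch set")
  if (!is.null(mined_fp) && n_patches(mined_fp))
    mined_fp$meta$label <- "non_cmb"
  switch(config$strategy,
    A = {
      pool <- bind_patches(cmb, non_cmb)
      undersample(pool, config$undersample_ratio, config$seed)
    },
    B = bind_patches(cmb, non_cmb),
    C = bind_patches(cmb, non_cmb, mined_fp),
    D = bind_patches(cmb, mined_fp))
}
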