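# Synthetic GRE/SWI-like phantoms: smooth tissue background, multiplicative
# hypointense spheroids (microbleeds), vessel- and artefact-like mimics,
# additive Gaussian noise, and exact per-scan ground truth.

#' Phantom generator configuration
#'
#' Defines the study conditions the phantom emulates: a smoothly varying
#' tissue background, hypointense spheroidal microbleeds whose centre
#' intensity drops by `lesion_contrast` relative to the local background,
#' tubular vessel-like and speckle artefact-like mimics, and additive
#' Gaussian acquisition noise. Intensities are arbitrary scanner units.
#'
#' @param volume_shape voxels per axis (each >= 11).
#' @param voxel_spacing mm per axis.
#' @param background_mean mean tissue intensity.
#' @param background_sd standard deviation of the smooth background field
#'   (tissue texture), not of the voxel noise.
#' @param lesion_radius_range min/max microbleed radius, voxels.
#' @param lesion_contrast fractional intensity drop at a microbleed centre,
#'   in (0, 1].
#' @param n_cmb_range min/max microbleed count per scan.
#' @param mimic_counts named integer vector with elements `vessel_mimic`
#'   and `artifact_mimic`: mimics inserted per scan.
#' @param noise_sd standard deviation of additive voxelwise Gaussian noise.
#' @param seed default seed used when an operation is not given one.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(64, 64, 64),
                           voxel_spacing = c(1, 1, 1),
                           background_mean = 100,
                           background_sd = 10,
                           lesion_radius_range = c(1, 3),
                           lesion_contrast = 0.6,
                           n_cmb_range = c(1, 4),
                           mimic_counts = c(vessel_mimic = 2,
                                            artifact_mimic = 3),
                           noise_sd = 5,
                           seed = 1L) {
  cfg <- list(volume_shape = as.integer(volume_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              background_mean = background_mean,
              background_sd = background_sd,
              lesion_radius_range = as.numeric(lesion_radius_range),
              lesion_contrast = lesion_contrast,
              n_cmb_range = as.integer(n_cmb_range),
              mimic_counts = mimic_counts,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid phantom config field `", field, "`: ", why)
  }
  chk(length(cfg$volume_shape) == 3 && all(cfg$volume_shape >= 11),
      "volume_shape", "each axis must be >= 11")
  chk(length(cfg$voxel_spacing) == 3 && all(cfg$voxel_spacing > 0),
      "voxel_spacing", "must be positive")
  chk(is.finite(cfg$background_mean) && cfg$background_mean > 0,
      "background_mean", "must be positive")
  chk(is.finite(cfg$background_sd) && cfg$background_sd >= 0,
      "background_sd", "must be nonnegative")
  chk(length(cfg$lesion_radius_range) == 2 &&
        cfg$lesion_radius_range[1] > 0 &&
        diff(cfg$lesion_radius_range) >= 0,
      "lesion_radius_range", "must be a nonempty positive range")
  chk(cfg$lesion_contrast > 0 && cfg$lesion_contrast <= 1,
      "lesion_contrast", "must lie in (0, 1]")
  chk(length(cfg$n_cmb_range) == 2 && cfg$n_cmb_range[1] >= 0 &&
        diff(cfg$n_cmb_range) >= 0,
      "n_cmb_range", "must be a nonempty nonnegative range")
  chk(all(c("vessel_mimic", "artifact_mimic") %in% names(cfg$mimic_counts)) &&
        all(cfg$mimic_counts >= 0),
      "mimic_counts", "needs nonnegative vessel_mimic and artifact_mimic")
  chk(is.finite(cfg$noise_sd) && cfg$noise_sd >= 0,
      "noise_sd", "must be nonnegative")
  invisible(cfg)
}

# R's Mersenne-Twister initialisation leaves streams for adjacent integer
# seeds offset by a single draw, so consecutive per-scan seeds would yield
# near-identical phantoms. A multiplicative (Knuth) hash decorrelates them.
scramble_seed <- function(seed) {
  as.integer(((as.double(seed) %% 65536 + 1) * 2654435761) %% 2147483647)
}

# Run expr under a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(scramble_seed(seed))
  expr
}

lesion_record <- function(center, radius, contrast, kind) {
  data.frame(x = center[1], y = center[2], z = center[3],
             radius = radius, contrast = contrast, kind = kind,
             stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(x = integer(0), y = integer(0), z = integer(0),
             radius = numeric(0), contrast = numeric(0),
             kind = character(0), stringsAsFactors = FALSE)
}

#' @export
print.labeled_volume <- function(x, ...) {
  k <- table(factor(x$records$kind,
                    levels = c("cmb", "vessel_mimic", "artifact_mimic")))
  cat(sprintf("<labeled_volume> scan '%s': %d cmb, %d vessel mimics, %d artifact mimics\n",
              x$scan_id, k[["cmb"]], k[["vessel_mimic"]],
              k[["artifact_mimic"]]))
  print(x$volume)
  invisible(x)
}

# Multiplicative Gaussian-profile stamp: factor 1 - contrast *
# exp(-d^2 / (2 (r/2)^2)) applied on a local cube of half-width 2r.
# Overlapping stamps of one structure combine by elementwise min so a
# tube built from sphere stamps does not compound darkening.
stamp_sphere <- function(factor_arr, center, radius, contrast) {
  d <- dim(factor_arr)
  hw <- ceiling(2 * radius)
  rng <- lapply(1:3, function(a)
    max(0L, center[a] - hw):min(d[a] - 1L, center[a] + hw))
  gx <- rng[[1]]; gy <- rng[[2]]; gz <- rng[[3]]
  dist2 <- outer(outer((gx - center[1])^2, (gy - center[2])^2, `+`),
                 (gz - center[3])^2, `+`)
  prof <- 1 - contrast * exp(-dist2 / (2 * (radius / 2)^2))
  sub <- factor_arr[gx + 1L, gy + 1L, gz + 1L, drop = FALSE]
  factor_arr[gx + 1L, gy + 1L, gz + 1L] <- pmin(sub, prof)
  factor_arr
}

# Smooth random field with unit sd: white noise blurred by a separable
# Gaussian, then rescaled.
smooth_field <- function(d, sigma = 4) {
  f <- array(stats::rnorm(prod(d)), dim = d)
  f <- gauss_smooth3d(f, sigma)
  sdev <- stats::sd(as.vector(f))
  if (sdev == 0) return(array(0, dim = d))
  f / sdev
}

free_positions <- function(d, margin) {
  lapply(1:3, function(a) margin:(d[a] - 1L - margin))
}

min_separation_ok <- function(center, placed, sep) {
  if (!nrow(placed)) return(TRUE)
  all(pmax(abs(placed$x - center[1]), abs(placed$y - center[2]),
           abs(placed$z - center[3])) >= sep)
}

draw_center <- function(d, margin, placed, sep, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    center <- c(sample(margin:(d[1] - 1L - margin), 1L),
                sample(margin:(d[2] - 1L - margin), 1L),
                sample(margin:(d[3] - 1L - margin), 1L))
    if (min_separation_ok(center, placed, sep)) return(center)
  }
  stop("could not place lesion: minimum centre separation of ", sep,
       " voxels exhausted the volume")
}

#' Insert hypointense spheroidal lesions into a volume
#'
#' Multiplies `n` radially symmetric hypointense profiles into a copy of
#' the volume; the intensity at each lesion centre drops by the drawn
#' contrast fraction. Centres keep a minimum Chebyshev separation of
#' `2 * max(radius_range) + 1` voxels so ground truth stays unambiguous
#' for patch labelling.
#'
#' @param volume a `cmb_volume` (unmodified by this call).
#' @param n number of lesions to insert.
#' @param radius_range min/max lesion radius in voxels.
#' @param contrast_range min/max fractional centre contrast in (0, 1].
#' @param seed RNG seed for this call.
#' @param kind record kind, default `"cmb"`.
#' @param avoid existing records data.frame whose centres must also be
#'   respected by the separation rule (optional).
#' @param scan_id scan identifier for the result.
#' @return A `labeled_volume`: list of `volume`, `records`, `scan_id`.
#' @export
insert_lesions <- function(volume, n, radius_range = c(1, 3),
                           contrast_range = c(0.6, 0.6), seed = 1L,
                           kind = "cmb", avoid = NULL,
                           scan_id = "scan") {
  stopifnot(inherits(volume, "cmb_volume"), n >= 0)
  if (!all(is.finite(volume$data))) stop("volume must be finite-valued")
  d <- dim(volume$data)
  rmax <- max(radius_range)
  sep <- 2 * ceiling(rmax) + 1
  margin <- ceiling(2 * rmax)
  if (n > 0 && any(d - 1L - 2L * margin < 0L))
    stop("lesions of radius ", rmax, " do not fit within the volume")
  recs <- empty_records()
  placed <- if (is.null(avoid)) empty_records() else avoid
  out <- volume$data
  with_seed(seed, {
    factor_arr <- array(1, dim = d)
    for (i in seq_len(n)) {
      radius <- stats::runif(1, radius_range[1], radius_range[2])
      contrast <- stats::runif(1, contrast_range[1], contrast_range[2])
      center <- draw_center(d, margin, placed, sep)
      factor_arr <- stamp_sphere(factor_arr, center, radius, contrast)
      rec <- lesion_record(center, radius, contrast, kind)
      recs <- rbind(recs, rec)
      placed <- rbind(placed, rec)
    }
    out <- out * factor_arr
  })
  structure(list(volume = cmb_volume(out, volume$affine),
                 records = recs, scan_id = scan_id),
            class = "labeled_volume")
}

insert_vessel_mimic <- function(factor_arr, placed, d, sep) {
  len_max <- min(16L, min(d) %/% 2L - 4L)
  if (len_max < 4L)
    stop("volume too small for a vessel mimic (each axis must be >= 16)")
  len <- sample(min(8L, len_max):len_max, 1L)
  margin <- ceiling(len / 2) + 2L
  center <- draw_center(d, margin, placed, sep)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  contrast <- stats::runif(1, 0.5, 0.8)
  for (t in seq(-len / 2, len / 2, by = 0.5)) {
    p <- round(center + t * dir)
    factor_arr <- stamp_sphere(factor_arr, p, 1, contrast)
  }
  list(factor_arr = factor_arr,
       record = lesion_record(center, 1, contrast, "vessel_mimic"))
}

insert_artifact_mimic <- function(factor_arr, placed, d, sep) {
  n_speck <- sample(3:7, 1L)
  center <- draw_center(d, 4L, placed, sep)
  contrast <- stats::runif(1, 0.5, 0.9)
  for (i in seq_len(n_speck)) {
    p <- center + sample(-2:2, 3L, replace = TRUE)
    p <- pmin(pmax(p, 0L), d - 1L)
    # single-voxel speckle: sharp drop, no smooth profile
    idx <- matrix(p + 1L, nrow = 1)
    factor_arr[idx] <- min(factor_arr[idx], 1 - contrast)
  }
  list(factor_arr = factor_arr,
       record = lesion_record(center, 1, contrast, "artifact_mimic"))
}

#' Generate one synthetic labelled scan
#'
#' Builds a smooth tissue background, inserts microbleeds and mimics per
#' the configuration, then adds voxelwise Gaussian noise. Deterministic
#' given `(config, seed)`.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param scan_id scan identifier.
#' @return A `labeled_volume`.
#' @export
generate_volume <- function(config, seed = config$seed,
                            scan_id = sprintf("scan%04d", seed)) {
  validate_phantom_config(config)
  d <- config$volume_shape
  affine <- diag(c(config$voxel_spacing, 1))
  rmax <- max(config$lesion_radius_range)
  sep <- 2 * ceiling(rmax) + 1
  with_seed(seed, {
    bg <- config$background_mean +
      config$background_sd * smooth_field(d)
    bg[bg < config$background_mean * 0.2] <- config$background_mean * 0.2
    n_cmb <- if (diff(config$n_cmb_range) == 0) config$n_cmb_range[1]
             else sample(config$n_cmb_range[1]:config$n_cmb_range[2], 1L)
    factor_arr <- array(1, dim = d)
    recs <- empty_records()
    margin <- ceiling(2 * rmax)
    for (i in seq_len(n_cmb)) {
      radius <- stats::runif(1, config$lesion_radius_range[1],
                             config$lesion_radius_range[2])
      center <- draw_center(d, margin, recs, sep)
      factor_arr <- stamp_sphere(factor_arr, center, radius,
                                 config$lesion_contrast)
      recs <- rbind(recs, lesion_record(center, radius,
                                        config$lesion_contrast, "cmb"))
    }
    for (i in seq_len(config$mimic_counts[["vessel_mimic"]])) {
      ins <- insert_vessel_mimic(factor_arr, recs, d, sep)
      factor_arr <- ins$factor_arr
      recs <- rbind(recs, ins$record)
    }
    for (i in seq_len(config$mimic_counts[["artifact_mimic"]])) {
      ins <- insert_artifact_mimic(factor_arr, recs, d, sep)
      factor_arr <- ins$factor_arr
      recs <- rbind(recs, ins$record)
    }
    x <- bg * factor_arr
    if (config$noise_sd > 0)
      x <- x + stats::rnorm(length(x), 0, config$noise_sd)
    dim(x) <- d
    structure(list(volume = cmb_volume(x, affine), records = recs,
                   scan_id = scan_id),
              class = "labeled_volume")
  })
}

#' Generate a cohort of phantom scans
#'
#' Generates `n_scans` labelled volumes of which exactly
#' `round(prevalence * n_scans)` contain at least one microbleed; the rest
#' are normal (zero-CMB) scans whose every detection is a false positive.
#' When `dir` is given, volumes are written as `.nii.gz`, annotations as a
#' CSV and the cohort manifest as JSON.
#'
#' @param config a [phantom_config()].
#' @param n_scans number of scans.
#' @param prevalence fraction of scans with at least one microbleed.
#' @param seed cohort seed; scan i uses `seed + i`.
#' @param dir optional output directory (created if missing).
#' @return A list with `scans` (list of `labeled_volume`) and `manifest`
#'   (data.frame: scan_id, path, n_cmb, seed).
#' @export
generate_cohort <- function(config, n_scans, prevalence = 1, seed = 1L,
                            dir = NULL) {
  validate_phantom_config(config)
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must lie in [0, 1]")
  n_pos <- round(prevalence * n_scans)
  pos <- with_seed(seed, sample(n_scans, n_pos))
  normal_cfg <- config
  normal_cfg$n_cmb_range <- c(0L, 0L)
  if (config$n_cmb_range[2] == 0 && n_pos > 0)
    stop("prevalence > 0 requires n_cmb_range with a positive upper bound")
  pos_cfg <- config
  pos_cfg$n_cmb_range <- pmax(config$n_cmb_range, c(1L, 1L))
  scans <- vector("list", n_scans)
  rows <- vector("list", n_scans)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_len(n_scans)) {
    cfg_i <- if (i %in% pos) pos_cfg else normal_cfg
    sid <- sprintf("scan%04d", i)
    lv <- generate_volume(cfg_i, seed = seed + i, scan_id = sid)
    scans[[i]] <- lv
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(sid, ".nii.gz"))
      write_volume(lv$volume, path)
    }
    rows[[i]] <- data.frame(scan_id = sid, path = path,
                            n_cmb = sum(lv$records$kind == "cmb"),
                            seed = seed + i, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    ann <- do.call(rbind, lapply(scans, function(lv) {
      if (!nrow(lv$records)) return(NULL)
      data.frame(scan_id = lv$scan_id, x = lv$records$x, y = lv$records$y,
                 z = lv$records$z, coord_space = "voxel",
                 kind = ifelse(lv$records$kind == "cmb", "cmb", "mimic"),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(ann)) ann <- NULL
    write_annotations(if (is.null(ann)) empty_records()[0, 0] else ann,
                      file.path(dir, "annotations.csv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  list(scans = scans, manifest = manifest)
}
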