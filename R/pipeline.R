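# End-to-end orchestration: phantom cohort -> normalisation -> patch
# extraction -> (optional) hard-negative mining -> strategy assembly ->
# training -> held-out evaluation. One global seed fans out to per-stage
# seeds by fixed offsets so stages can be re-run in isolation.

stage_seed <- function(seed, stage) {
  offs <- c(phantom = 1000L, patching = 2000L, training = 3000L,
            mining = 4000L, evaluation = 5000L)
  seed + offs[[stage]]
}

normalize_scan <- function(lvol) {
  lvol$volume <- normalize_volume(lvol$volume)
  lvol
}

#' Extract training patches from a cohort
#'
#' Normalises every scan, then extracts lesion-centred CMB patches and a
#' sliding-window non-CMB pool (tiles touching any microbleed sphere are
#' excluded to avoid label noise).
#'
#' @param scans list of `labeled_volume` objects.
#' @param spec a [patch_spec()].
#' @return List with patch sets `cmb` (provenance `centered`) and
#'   `non_cmb` (provenance `sliding`).
#' @export
cohort_patches <- function(scans, spec = patch_spec()) {
  scans <- lapply(scans, normalize_scan)
  pos <- lapply(scans, extract_centered, spec = spec)
  neg <- lapply(scans, function(lv) {
    s <- extract_sliding(lv, spec, exclude_cmb_margin = TRUE)
    if (n_patches(s)) subset_patches(s, which(s$meta$label == "non_cmb"))
    else s
  })
  list(cmb = do.call(bind_patches, pos),
       non_cmb = do.call(bind_patches, neg))
}

#' Mine hard negatives over a cohort
#'
#' Runs the candidate proposer on every (normalised) scan, partitions
#' candidates against the scan's ground truth, and harvests the false
#' positives as `mined_fp` patches.
#'
#' @param scans list of `labeled_volume` objects.
#' @param config a [proposer_config()].
#' @param spec a [patch_spec()].
#' @return List with `patches` (pooled FP `patch_set`) and `report`
#'   (per-scan data.frame: scan_id, n_candidates, tp, fp).
#' @export
mine_cohort <- function(scans, config = proposer_config(),
                        spec = patch_spec()) {
  scans <- lapply(scans, normalize_scan)
  sets <- list()
  rows <- list()
  for (lv in scans) {
    cand <- propose_candidates(lv$volume, config)
    parts <- match_candidates(cand, lv$records, config$match_radius)
    sets[[length(sets) + 1]] <-
      harvest_fp_patches(lv$volume, parts$fp, spec, lv$scan_id)
    rows[[length(rows) + 1]] <-
      data.frame(scan_id = lv$scan_id, n_candidates = nrow(cand),
                 tp = nrow(parts$tp), fp = nrow(parts$fp),
                 stringsAsFactors = FALSE)
  }
  list(patches = do.call(bind_patches, c(sets, list(empty_patch_set(spec$edge)))),
       report = do.call(rbind, rows))
}

#' Count surviving false positives on normal scans
#'
#' Proposes candidates on each scan, classifies the candidate-centred
#' patches with a fitted network, and counts those called `cmb`. On
#' normal (zero-CMB) scans every such call is a false positive.
#'
#' @param net a fitted `cmb_net`.
#' @param scans list of `labeled_volume` objects (typically normal).
#' @param config a [proposer_config()].
#' @param spec a [patch_spec()].
#' @return List with `n_fp` (count), `n_scans` and `per_scan` data.frame.
#' @export
count_normal_fps <- function(net, scans, config = proposer_config(),
                             spec = patch_spec()) {
  scans <- lapply(scans, normalize_scan)
  rows <- list()
  total <- 0L
  for (lv in scans) {
    cand <- propose_candidates(lv$volume, config)
    n_pos <- 0L
    if (nrow(cand)) {
      patches <- harvest_fp_patches(lv$volume, cand, spec, lv$scan_id)
      pred <- predict(net, patches, type = "class")
      n_pos <- sum(pred == "cmb")
    }
    total <- total + n_pos
    rows[[length(rows) + 1]] <-
      data.frame(scan_id = lv$scan_id, n_candidates = nrow(cand),
                 n_fp = n_pos, stringsAsFactors = FALSE)
  }
  list(n_fp = total, n_scans = length(scans),
       per_scan = do.call(rbind, rows))
}

default_run_config <- function() {
  phantom_fields <- unclass(phantom_config())
  phantom_fields$seed <- NULL  # the stage seed governs generation
  list(seed = 1L,
       phantom = c(list(n_scans = 10L, prevalence = 0.8), phantom_fields),
       patching = list(edge = 11L, stride = 11L),
       strategy = list(strategy = "A", undersample_ratio = 1),
       model = list(preset = "full"),
       training = list(lr = 0.01, weight_decay = 1e-4, epochs = 20L,
                       batch_size = 128L, augment_copies = 8L),
       mining = list(scales = c(1, 2, 3), response_threshold = 1,
                     max_candidates = 50L, match_radius = 5L),
       evaluation = list(heldout_fraction = 0.25))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- user[[nm]]
  }
  base
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Build the model requested by a run configuration
#'
#' `preset = "full"` is the production architecture; `"small"` is a
#' reduced schedule (8/16/32 filters, one conv per stage, 64-unit head)
#' for quick experiments.
#'
#' @param model_cfg list with a `preset` element.
#' @param edge patch edge length.
#' @return A `cmb_model`.
#' @export
model_from_config <- function(model_cfg, edge = 11L) {
  preset <- model_cfg$preset %||% "full"
  switch(preset,
         full = cmb_model(edge = edge),
         small = cmb_model(conv_blocks = list(c(8, 1), c(16, 1), c(32, 1)),
                           dropout = c(0.3, 0.3, 0.4), head_width = 64L,
                           edge = edge),
         stop("unknown model preset: ", preset))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' simulate -> extract -> (mine, strategies C/D) -> assemble -> train ->
#' evaluate. Held-out scans (the trailing `heldout_fraction` of the
#' cohort) supply exhaustive sliding-window evaluation patches plus
#' normal-scan false-positive counts via the candidate proposer.
#'
#' @param config nested list as in the run-configuration schema; missing
#'   keys take defaults, unknown keys are rejected.
#' @param seed overrides `config$seed` when given.
#' @param out optional output directory for the manifest and report JSON.
#' @return A list with `report` (metrics, counts, FP rates), `net`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out = NULL) {
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  seed <- cfg$seed
  t0 <- Sys.time()

  # simulate
  pcfg_fields <- setdiff(names(cfg$phantom), c("n_scans", "prevalence"))
  pcfg <- do.call(phantom_config, cfg$phantom[pcfg_fields])
  cohort <- generate_cohort(pcfg, cfg$phantom$n_scans,
                            cfg$phantom$prevalence,
                            seed = stage_seed(seed, "phantom"))
  n_scans <- length(cohort$scans)
  n_held <- max(1L, round(cfg$evaluation$heldout_fraction * n_scans))
  # stratified hold-out: split positive and normal scans proportionally
  # so both sides of the split see both scan types where possible
  pos_idx <- which(cohort$manifest$n_cmb > 0)
  neg_idx <- which(cohort$manifest$n_cmb == 0)
  held_idx <- with_seed(stage_seed(seed, "evaluation"), {
    n_pos_held <- min(max(0L, length(pos_idx) - 1L),
                      round(n_held * length(pos_idx) / n_scans))
    n_neg_held <- min(length(neg_idx), n_held - n_pos_held)
    c(if (n_pos_held > 0) sample(pos_idx, n_pos_held),
      if (n_neg_held > 0) sample(neg_idx, n_neg_held))
  })
  held <- cohort$scans[held_idx]
  train_scans <- cohort$scans[setdiff(seq_len(n_scans), held_idx)]

  # extract
  spec <- patch_spec(cfg$patching$edge, cfg$patching$stride)
  tr <- cohort_patches(train_scans, spec)

  # mine (strategies C/D)
  strat <- cfg$strategy$strategy
  mcfg <- proposer_config(cfg$mining$scales, cfg$mining$response_threshold,
                          cfg$mining$max_candidates, cfg$mining$match_radius)
  mined <- NULL
  mine_report <- NULL
  if (strat %in% c("C", "D")) {
    mres <- mine_cohort(train_scans, mcfg, spec)
    mined <- mres$patches
    mine_report <- mres$report
  }

  # assemble + train; positives are enriched by concatenating stochastic
  # augmented copies, the standard countermeasure to class imbalance here
  pos <- tr$cmb
  if (cfg$training$augment_copies > 0)
    pos <- augment_set(pos, augment_config(
      copies_per_sample = cfg$training$augment_copies,
      seed = stage_seed(seed, "patching")))
  scfg <- strategy_config(strat, cfg$strategy$undersample_ratio,
                          seed = stage_seed(seed, "patching"))
  train_set <- assemble_training_set(scfg, pos, tr$non_cmb, mined)
  model <- model_from_config(cfg$model, spec$edge)
  ctrl <- cmb_control(lr = cfg$training$lr,
                      weight_decay = cfg$training$weight_decay,
                      epochs = cfg$training$epochs,
                      batch_size = cfg$training$batch_size,
                      seed = stage_seed(seed, "training"))
  net <- cmb_train(train_set, model = model, control = ctrl)

  # evaluate on held-out scans: lesion-centred positives (the adopted
  # centralised-CMB scheme; deployment classifies candidate-centred
  # patches) plus the exhaustive sliding non-CMB pool
  held_ext <- cohort_patches(held, spec)
  ev <- bind_patches(held_ext$cmb, held_ext$non_cmb)
  scores <- predict(net, ev)
  truth <- as.integer(ev$meta$label == "cmb")
  cc <- confusion(truth, as.integer(scores > 0.5))
  rep_ <- metric_report(cc, truth, scores)
  normals <- held[vapply(held, function(lv)
    sum(lv$records$kind == "cmb") == 0, TRUE)]
  fp_norm <- if (length(normals))
    count_normal_fps(net, normals, mcfg, spec) else NULL

  report <- list(
    strategy = strat,
    n_train_patches = n_patches(train_set),
    train_class_counts = as.list(class_counts(train_set)),
    heldout_scans = length(held),
    heldout_metrics = rep_,
    heldout_counts = list(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
    normal_scan_fp = if (!is.null(fp_norm))
      list(n_fp = fp_norm$n_fp, n_scans = fp_norm$n_scans,
           per_scan_rate = per_scan_fp_rate(fp_norm$n_fp,
                                            fp_norm$n_scans)) else NULL,
    mined_fp_total = if (!is.null(mine_report)) sum(mine_report$fp)
                     else NULL,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   seed = seed,
                   stage_seeds = lapply(c("phantom", "patching", "training",
                                          "mining", "evaluation"),
                                        function(s) stage_seed(seed, s)),
                   created = format(t0, "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, net = net, manifest = manifest)
}
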