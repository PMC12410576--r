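# On-disk interchange for cohorts and patch sets: NIfTI volumes plus CSV
# annotations for cohorts; a gzipped CSV block matrix plus a JSON manifest
# for patch sets.

#' Read a phantom cohort from disk
#'
#' Loads the `manifest.json`, each scan's NIfTI volume and the cohort
#' annotation CSV written by [generate_cohort()].
#'
#' @param dir cohort directory.
#' @return A list with `scans` (list of `labeled_volume`) and `manifest`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", dir)
  manifest <- jsonlite::fromJSON(mf)
  ann_path <- file.path(dir, "annotations.csv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  scans <- lapply(seq_len(nrow(manifest)), function(i) {
    vol <- read_volume(manifest$path[i])
    sid <- manifest$scan_id[i]
    rows <- if (!is.null(ann)) ann[ann$scan_id == sid, , drop = FALSE]
            else NULL
    recs <- if (is.null(rows) || !nrow(rows)) empty_records()
    else data.frame(x = rows$x, y = rows$y, z = rows$z,
                    radius = NA_real_, contrast = NA_real_,
                    kind = ifelse(rows$kind == "cmb", "cmb",
                                  "artifact_mimic"),
                    stringsAsFactors = FALSE)
    structure(list(volume = vol, records = recs, scan_id = sid),
              class = "labeled_volume")
  })
  list(scans = scans, manifest = manifest)
}

#' Write a patch set to disk
#'
#' Stores the intensity blocks as a gzipped CSV (one row per patch) and
#' the metadata as a JSON manifest.
#'
#' @param ps a `patch_set`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patch_set <- function(ps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  con <- gzfile(file.path(dir, "blocks.csv.gz"), "w")
  utils::write.table(t(ps$x), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  jsonlite::write_json(list(edge = ps$edge, n = n_patches(ps),
                            meta = ps$meta),
                       file.path(dir, "patches.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a patch set written by [write_patch_set()]
#'
#' @param dir patch-set directory.
#' @return A `patch_set`.
#' @export
read_patch_set <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "patches.json"))
  meta <- as.data.frame(man$meta, stringsAsFactors = FALSE)
  if (man$n == 0) return(empty_patch_set(man$edge))
  x <- t(as.matrix(utils::read.table(
    gzfile(file.path(dir, "blocks.csv.gz")), sep = ",")))
  dimnames(x) <- NULL
  patch_set(x, meta, man$edge)
}
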