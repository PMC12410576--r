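# Shared in-code fixtures: tiny volumes and synthetic patch sets.

flat_volume <- function(d = c(20, 20, 20), value = 100, affine = diag(4)) {
  cmb_volume(array(value, dim = d), affine)
}

# a labelled volume with known record positions and no randomness
manual_labeled_volume <- function(d = c(33, 33, 33), centers = NULL,
                                  value = 100, scan_id = "manual") {
  recs <- if (is.null(centers)) {
    data.frame(x = integer(0), y = integer(0), z = integer(0),
               radius = numeric(0), contrast = numeric(0),
               kind = character(0), stringsAsFactors = FALSE)
  } else {
    data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
               radius = 2, contrast = 0.5, kind = "cmb",
               stringsAsFactors = FALSE)
  }
  structure(list(volume = flat_volume(d, value), records = recs,
                 scan_id = scan_id),
            class = "labeled_volume")
}

# synthetic patch set with given class sizes; intensities are random but
# the two classes are offset so simple learners can separate them
toy_patch_set <- function(n_cmb, n_non, edge = 5L, seed = 1,
                          scan_id = "toy", provenance = "sliding",
                          offset = 3) {
  n <- n_cmb + n_non
  if (n == 0) return(empty_patch_set(edge))
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(edge^3 * n), edge^3, n)
    if (n_cmb > 0)
      x[ceiling(edge^3 / 2), seq_len(n_cmb)] <-
        x[ceiling(edge^3 / 2), seq_len(n_cmb)] - offset
  })
  meta <- data.frame(scan_id = scan_id, cx = seq_len(n), cy = 0L, cz = 0L,
                     label = rep(c("cmb", "non_cmb"), c(n_cmb, n_non)),
                     provenance = provenance, stringsAsFactors = FALSE)
  patch_set(x, meta, edge)
}

tiny_model <- function(edge = 5L) {
  cmb_model(conv_blocks = list(c(4, 1), c(8, 1)), dropout = c(0.1, 0.1),
            head_width = 8L, head_dropout = 0.1, edge = edge)
}

small_model <- function(edge = 11L) {
  cmb_model(conv_blocks = list(c(8, 1), c(16, 1), c(32, 1)),
            dropout = c(0.3, 0.3, 0.4), head_width = 64L, edge = edge)
}
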