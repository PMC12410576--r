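test_that("sliding tiling drops partial windows and partitions the crop", {
  lv33 <- manual_labeled_volume(d = c(33, 33, 33))
  ps <- extract_sliding(lv33)
  expect_equal(n_patches(ps), 27L)
  expect_true(all(ps$meta$label == "non_cmb"))

  lv34 <- manual_labeled_volume(d = c(34, 34, 34))
  expect_equal(n_patches(extract_sliding(lv34)), 27L)

  # partition: reassembling the tiles reproduces the cropped region
  arr <- array(rnorm(33^3), dim = c(33, 33, 33))
  lv33$volume <- cmb_volume(arr)
  ps <- extract_sliding(lv33)
  rebuilt <- array(NA_real_, dim = c(33, 33, 33))
  for (i in seq_len(n_patches(ps))) {
    o <- c(ps$meta$cx[i], ps$meta$cy[i], ps$meta$cz[i]) - 5L
    rebuilt[o[1] + 1:11, o[2] + 1:11, o[3] + 1:11] <-
      array(ps$x[, i], dim = c(11, 11, 11))
  }
  expect_identical(rebuilt, arr)  # every voxel in exactly one tile
})

test_that("sliding labels follow the centre-containment rule", {
  lv <- manual_labeled_volume(d = c(33, 33, 33),
                              centers = rbind(c(5, 5, 5)))
  ps <- extract_sliding(lv)
  lab <- ps$meta$label
  first_tile <- which(ps$meta$cx == 5 & ps$meta$cy == 5 & ps$meta$cz == 5)
  expect_equal(lab[first_tile], "cmb")
  expect_equal(sum(lab == "cmb"), 1L)
})

test_that("sliding labels agree with a brute-force containment oracle", {
  cfg <- phantom_config(volume_shape = c(34, 34, 34), n_cmb_range = c(2, 3),
                        mimic_counts = c(vessel_mimic = 0,
                                         artifact_mimic = 0))
  for (s in 1:5) {
    lv <- generate_volume(cfg, seed = s)
    ps <- extract_sliding(lv)
    cc <- lv$records[lv$records$kind == "cmb", ]
    for (i in seq_len(n_patches(ps))) {
      o <- c(ps$meta$cx[i], ps$meta$cy[i], ps$meta$cz[i]) - 5L
      expected <- FALSE
      for (j in seq_len(nrow(cc)))
        if (all(c(cc$x[j], cc$y[j], cc$z[j]) >= o) &&
            all(c(cc$x[j], cc$y[j], cc$z[j]) <= o + 10))
          expected <- TRUE
      expect_equal(ps$meta$label[i] == "cmb", expected)
    }
  }
})

test_that("centred extraction spans the lesion and shifts at boundaries", {
  lv <- manual_labeled_volume(d = c(40, 40, 40),
                              centers = rbind(c(20, 20, 20), c(2, 2, 2)))
  arr <- array(rnorm(40^3), dim = c(40, 40, 40))
  lv$volume <- cmb_volume(arr)
  ps <- extract_centered(lv)
  expect_equal(n_patches(ps), 2L)
  expect_true(all(ps$meta$label == "cmb"))
  expect_true(all(ps$meta$provenance == "centered"))
  # interior record: block spans 15..25 on each axis
  expect_equal(ps$x[, 1], as.vector(arr[16:26, 16:26, 16:26]))
  expect_equal(unlist(ps$meta[1, c("cx", "cy", "cz")], use.names = FALSE),
               c(20L, 20L, 20L))
  # boundary record: window shifted to span 0..10
  expect_equal(ps$x[, 2], as.vector(arr[1:11, 1:11, 1:11]))
  # record still inside the shifted block
  expect_true(all(abs(unlist(ps$meta[2, c("cx", "cy", "cz")]) -
                        c(2, 2, 2)) <= 5))
})

test_that("undersampling keeps all positives and a seeded negative subset", {
  ps <- toy_patch_set(100, 1000)
  out <- undersample(ps, ratio = 1, seed = 7)
  expect_equal(unname(class_counts(out)), c(100L, 100L))
  out2 <- undersample(ps, ratio = 1, seed = 7)
  expect_identical(out$meta, out2$meta)
  out3 <- undersample(ps, ratio = 1, seed = 8)
  expect_false(identical(out$meta, out3$meta))
  expect_warning(big <- undersample(ps, ratio = 20, seed = 1), "pool")
  expect_equal(unname(class_counts(big)), c(100L, 1000L))
  neg_only <- subset_patches(ps, which(ps$meta$label == "non_cmb"))
  expect_error(undersample(neg_only, 1, 1), "cmb")
})

test_that("the four assembly strategies compose the documented sets", {
  cmb <- toy_patch_set(100, 0, scan_id = "pos", provenance = "centered")
  non <- toy_patch_set(0, 1000, scan_id = "neg")
  mined <- toy_patch_set(0, 238, scan_id = "mine", provenance = "mined_fp")
  mined$meta$label <- "cmb"  # must be forced back to non_cmb on assembly

  a <- assemble_training_set(strategy_config("A", 1, seed = 1), cmb, non)
  expect_equal(n_patches(a), 200L)
  b <- assemble_training_set(strategy_config("B"), cmb, non)
  expect_equal(n_patches(b), 1100L)
  c_ <- assemble_training_set(strategy_config("C"), cmb, non, mined)
  expect_equal(n_patches(c_), 1338L)
  d <- assemble_training_set(strategy_config("D"), cmb, non, mined)
  expect_equal(n_patches(d), 338L)
  expect_true(all(d$meta$label[d$meta$provenance == "mined_fp"] ==
                    "non_cmb"))
  expect_error(assemble_training_set(strategy_config("C"), cmb, non),
               "mined_fp")
  expect_error(assemble_training_set(strategy_config("D"), cmb, non,
                                     empty_patch_set(5L)), "mined_fp")
})

test_that("patch sets reject malformed construction", {
  ps <- toy_patch_set(2, 2)
  expect_error(patch_set(ps$x, ps$meta[1:3, ], ps$edge), "match")
  bad <- ps$meta
  bad$label[1] <- "weird"
  expect_error(patch_set(ps$x, bad, ps$edge), "label")
  dup <- ps$meta
  dup$cx <- 1L
  expect_error(patch_set(ps$x, dup, ps$edge), "duplicate")
})

test_that("patch sets round-trip through the on-disk format", {
  ps <- toy_patch_set(3, 4)
  dir <- file.path(tempdir(), "ps-test")
  write_patch_set(ps, dir)
  back <- read_patch_set(dir)
  expect_equal(back$x, ps$x, tolerance = 1e-12)
  expect_equal(back$meta, ps$meta)
  expect_equal(back$edge, ps$edge)
  unlink(dir, recursive = TRUE)
})
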