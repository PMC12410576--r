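test_that("the default architecture matches the documented layer table", {
  m <- cmb_model()
  expect_equal(architecture_audit(m),
               c("Conv+BN+ReLU 32x3x3x3", "Conv+BN+ReLU 32x3x3x3",
                 "MaxPool 2x2x2", "Dropout 0.3",
                 "Conv+BN+ReLU 64x3x3x3", "Conv+BN+ReLU 64x3x3x3",
                 "MaxPool 2x2x2", "Dropout 0.3",
                 "Conv+BN+ReLU 128x3x3x3", "Conv+BN+ReLU 128x3x3x3",
                 "MaxPool 2x2x2", "Dropout 0.4",
                 "Linear 256", "Dropout 0.4", "Linear 2"))
  expect_equal(spatial_schedule(11), c(11L, 5L, 2L, 1L))
  expect_error(cmb_model(edge = 5), "too small")
  expect_error(cmb_model(dropout = c(0.3, 0.3)), "dropout")
})

test_that("parameter count equals the closed-form per-layer summation", {
  # independent oracle: conv = Cout*(Cin*27) + Cout, BN = 2*C,
  # linear = out*in + out, summed over the layer table
  conv <- function(cin, cout) cout * cin * 27 + cout + 2 * cout
  oracle <- conv(1, 32) + conv(32, 32) + conv(32, 64) + conv(64, 64) +
    conv(64, 128) + conv(128, 128) +
    (256 * 128 + 256) + (2 * 256 + 2)
  expect_equal(count_parameters(cmb_model()), oracle)
})

test_that("training learns separable toy patches deterministically", {
  tr <- toy_patch_set(12, 12, edge = 5, offset = 6)
  ctrl <- cmb_control(epochs = 8, batch_size = 8, seed = 2, lr = 0.005)
  net <- cmb_train(tr, model = tiny_model(5), control = ctrl)
  expect_s3_class(net, "cmb_net")
  expect_true(all(is.finite(net$history$loss)))
  expect_equal(nrow(net$history), 8L)

  # identical seed => identical history and weights
  net2 <- cmb_train(tr, model = tiny_model(5), control = ctrl)
  expect_identical(net$history, net2$history)
  expect_identical(net$params, net2$params)

  p <- predict(net, tr)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(length(predict(net, toy_patch_set(0, 0, edge = 5))), 0L)
  lab <- predict(net, tr, type = "class")
  expect_true(all(lab %in% c("cmb", "non_cmb")))
})

test_that("training refuses single-class sets and mismatched edges", {
  ps <- toy_patch_set(0, 10, edge = 5)
  expect_error(cmb_train(ps, model = tiny_model(5)), "both classes")
  tr <- toy_patch_set(4, 4, edge = 5)
  expect_error(cmb_train(tr, model = tiny_model(7)), "edge")
})

test_that("validation model selection keeps the best epoch", {
  tr <- toy_patch_set(12, 12, edge = 5, offset = 6, seed = 1)
  va <- toy_patch_set(6, 6, edge = 5, offset = 6, seed = 2)
  net <- cmb_train(tr, val = va, model = tiny_model(5),
                   control = cmb_control(epochs = 6, batch_size = 8,
                                         seed = 1, lr = 0.005))
  expect_true(net$best_epoch >= 1 && net$best_epoch <= 6)
  best <- max(net$history$val_bacc, na.rm = TRUE)
  expect_equal(net$history$val_bacc[net$best_epoch], best)
  # ties resolve to the earliest epoch achieving the maximum
  expect_equal(net$best_epoch, which.max(net$history$val_bacc))
})

test_that("fine-tuning resumes from supplied weights", {
  tr <- toy_patch_set(10, 10, edge = 5, offset = 6)
  ctrl <- cmb_control(epochs = 3, batch_size = 8, seed = 3, lr = 0.005)
  pre <- cmb_train(tr, model = tiny_model(5), control = ctrl)
  tuned <- cmb_train(tr, model = tiny_model(5), control = ctrl, init = pre)
  expect_false(identical(pre$params$fc2_W, tuned$params$fc2_W))
  # warm start should not do worse on the training data it continued on
  expect_lte(tail(tuned$history$loss, 1), tail(pre$history$loss, 1) + 0.1)
})

test_that("flips are involutions and augmentation preserves labels", {
  v <- rnorm(5^3)
  for (axis in 1:2)
    expect_identical(cmbkit:::flip_patch(cmbkit:::flip_patch(v, 5L, axis),
                                         5L, axis), v)

  ps <- toy_patch_set(5, 5, edge = 5)
  out <- augment_set(ps, augment_config(copies_per_sample = 2, seed = 9))
  expect_equal(n_patches(out), 3 * n_patches(ps))
  new <- out$meta$provenance == "augmented"
  expect_equal(sum(new), 2 * n_patches(ps))
  expect_equal(out$meta$label[new],
               rep(ps$meta$label, 2))
  expect_error(augment_config(transforms = "sharpen"), "sharpen")
  # flips-only augmentation permutes voxels, never changes their values
  flip_only <- augment_set(ps, augment_config(
    transforms = c("flip_vertical", "flip_horizontal"), seed = 4))
  for (i in seq_len(n_patches(ps)))
    expect_equal(sort(flip_only$x[, n_patches(ps) + i]), sort(ps$x[, i]))
})

test_that("prediction probabilities are complementary softmax outputs", {
  tr <- toy_patch_set(8, 8, edge = 5, offset = 6)
  net <- cmb_train(tr, model = tiny_model(5),
                   control = cmb_control(epochs = 2, batch_size = 8,
                                         seed = 1, lr = 0.005))
  p <- predict(net, tr)
  lab <- predict(net, tr, type = "class")
  expect_identical(lab, ifelse(p > 0.5, "cmb", "non_cmb"))
  expect_true(all(p > 0 & p < 1))
})
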