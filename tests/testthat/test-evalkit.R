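test_that("confusion tallies agree with an independent counting oracle", {
  expect_error(confusion(c(1, 0), c(1)), "lengths")
  all_right <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(all_right$fp, all_right$fn), c(0, 0))
  all_wrong <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(all_wrong$tp, all_wrong$tn), c(0, 0))

  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- sample(5:50, 1)
      y <- sample(0:1, n, replace = TRUE)
      p <- sample(0:1, n, replace = TRUE)
      cc <- confusion(y, p)
      # oracle: elementwise tally
      expect_equal(cc$tp, sum(y & p))
      expect_equal(cc$fp, sum(!y & p))
      expect_equal(cc$fn, sum(y & !p))
      expect_equal(cc$tn, sum(!y & !p))
      expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
    }
  })
  # string labels are accepted with cmb = positive
  cc <- confusion(c("cmb", "non_cmb"), c("cmb", "cmb"))
  expect_equal(c(cc$tp, cc$fp), c(1, 1))
})

test_that("metrics hit the analytic corner cases and flag degeneracy", {
  perfect <- confusion_counts(10, 0, 0, 90)
  expect_equal(as.numeric(balanced_accuracy(perfect)), 1)
  expect_equal(as.numeric(f1_score(perfect)), 1)
  coin <- confusion_counts(50, 50, 50, 50)
  expect_equal(as.numeric(balanced_accuracy(coin)), 0.5)

  no_pos_pred <- confusion_counts(0, 0, 5, 95)
  expect_equal(as.numeric(precision(no_pos_pred)), 0)
  expect_true(attr(precision(no_pos_pred), "degenerate"))
  normal_scan <- confusion_counts(0, 3, 0, 97)
  expect_equal(as.numeric(sensitivity(normal_scan)), 0)
  expect_true(attr(sensitivity(normal_scan), "degenerate"))
  expect_error(confusion_counts(-1, 0, 0, 5), "nonnegative")
})

test_that("rank-sum AUC matches brute-force pair counting and pROC", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_true(attr(roc_auc(c(1, 1), c(0.2, 0.3)), "degenerate"))

  pair_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(6:30, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(rnorm(n), 1)  # coarse scores force ties
      expect_equal(roc_auc(y, s), pair_auc(y, s))
    }
    y <- c(rep(0, 40), rep(1, 40))
    s <- rnorm(80) + y
    expect_equal(roc_auc(y, s),
                 as.numeric(pROC::auc(y, s, quiet = TRUE)))
  })
})

test_that("burden categories partition counts as 1-4 / 5-9 / >=10", {
  expect_equal(categorize_scan(0), "normal")
  expect_equal(categorize_scan(1), 1L)
  expect_equal(categorize_scan(4), 1L)
  expect_equal(categorize_scan(5), 2L)
  expect_equal(categorize_scan(9), 2L)
  expect_equal(categorize_scan(10), 3L)
  expect_equal(categorize_scan(500), 3L)
  expect_error(categorize_scan(-1), "nonnegative")
})

test_that("stratified reports micro-pool counts within category", {
  per_scan <- data.frame(
    scan_id = c("a", "b", "c", "d"),
    n_cmb = c(2, 3, 7, 0),
    tp = c(2, 2, 6, 0), fp = c(1, 0, 2, 3),
    fn = c(0, 1, 1, 0), tn = c(120, 119, 115, 122))
  rep_ <- stratified_report(per_scan)
  # category 1 pools scans a and b
  expect_equal(rep_$cat1$counts$tp, 4)
  expect_equal(as.numeric(rep_$cat1$sensitivity), 4 / 5)
  # single-category check: cat2 equals its only scan
  expect_equal(as.numeric(rep_$cat2$precision), 6 / 8)
  # zero-CMB scan appears under normal with only fp/tn
  expect_equal(rep_$normal$counts$tp, 0)
  expect_equal(rep_$normal$counts$fp, 3)
  expect_true(rep_$normal$degenerate_flags[["sensitivity"]])
  # overall equals pooling everything (recompute oracle)
  expect_equal(as.numeric(rep_$overall$precision),
               sum(per_scan$tp) / (sum(per_scan$tp) + sum(per_scan$fp)))
  # absent category omitted
  expect_null(rep_$cat3)
})

test_that("fold construction balances positives and honours grouping", {
  ps <- toy_patch_set(10, 40)
  plan <- make_folds(ps, k = 5, seed = 1)
  expect_equal(sort(unique(plan$fold)), 1:5)
  pos_per_fold <- table(plan$fold[ps$meta$label == "cmb"])
  expect_true(all(pos_per_fold == 2))
  expect_equal(length(plan$fold), n_patches(ps))
  expect_error(make_folds(toy_patch_set(3, 20), k = 5), "cmb")

  # grouped: patches of one scan never span folds
  sets <- lapply(1:6, function(i)
    toy_patch_set(2, 8, seed = i, scan_id = paste0("s", i)))
  pooled <- do.call(bind_patches, sets)
  gplan <- make_folds(pooled, k = 3, seed = 2, group_by_scan = TRUE)
  per_scan_folds <- tapply(gplan$fold, pooled$meta$scan_id,
                           function(f) length(unique(f)))
  expect_true(all(per_scan_folds == 1))
})

test_that("repeated CV runs k x repeats cells with disjoint test folds", {
  ps <- toy_patch_set(10, 40)
  # trivial always-negative classifier: analytic confusion counts
  res <- run_repeated_cv(ps,
                         train_fn = function(tr, s) NULL,
                         predict_fn = function(fit, te)
                           rep(0, n_patches(te)),
                         k = 5, repeats = 5, seed = 3)
  expect_equal(nrow(res$cells), 25L)
  expect_true(all(res$cells$tp == 0))
  expect_true(all(res$cells$fp == 0))
  expect_equal(sum(res$cells$fn), 5 * 10)  # every positive missed once
  expect_equal(sum(res$cells$tn), 5 * 40)
  # per repeat, folds exhaust the set exactly once
  for (r in 1:5) {
    rows <- res$cells[res$cells$repeat_ == r, ]
    expect_equal(sum(rows$tp + rows$fp + rows$fn + rows$tn),
                 n_patches(ps))
  }
})

test_that("CV aggregation averages folds within repeat, then repeats", {
  cells <- expand.grid(repeat_ = 1:3, fold = 1:2)
  cells$fp <- c(1, 3, 5, 3, 5, 7)  # repeat means 2, 4, 6
  agg <- aggregate_cv(cells)
  expect_equal(unname(agg$mean[["fp"]]), 4)
  expect_equal(unname(agg$sd[["fp"]]), 2)  # sample sd of (2,4,6)
  same <- cells; same$fp <- 5
  expect_equal(unname(aggregate_cv(same)$sd[["fp"]]), 0)
  one <- cells[cells$repeat_ == 1, ]
  expect_null(aggregate_cv(one)$sd)
})
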