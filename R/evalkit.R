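# Confusion-count metrics, burden-stratified reporting, and repeated
# stratified k-fold cross-validation with mean/std aggregation.

#' Confusion counts
#'
#' Counts may be non-integer reals so fold-averaged confusion tables can
#' be fed back through the metric formulas.
#'
#' @param tp,fp,fn,tn nonnegative counts; at least one must be positive.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || !any(v > 0))
    stop("confusion counts must be nonnegative with at least one positive")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %g  FP %g  FN %g  TN %g\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

as_binary01 <- function(v) {
  if (is.character(v) || is.factor(v)) as.integer(as.character(v) == "cmb")
  else as.integer(as.logical(v))
}

#' Tally a confusion matrix from label vectors
#'
#' @param truth,predicted equal-length binary vectors; `"cmb"`/`"non_cmb"`
#'   strings, logicals, or 0/1 with 1 = positive.
#' @return A [confusion_counts()] object.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  y <- as_binary01(truth)
  p <- as_binary01(predicted)
  confusion_counts(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
                   fn = sum(y == 1 & p == 0), tn = sum(y == 0 & p == 0))
}

ratio_or_flag <- function(num, den) {
  if (den <= 0) structure(0, degenerate = TRUE) else num / den
}

#' Balanced accuracy
#'
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`, the mean of sensitivity and
#' specificity. If one class is absent its term is counted as 0 and the
#' result carries a `degenerate` attribute.
#'
#' @param cc a `confusion_counts`.
#' @return Numeric in `[0, 1]`; attribute `degenerate = TRUE` when a
#'   denominator was zero.
#' @export
balanced_accuracy <- function(cc) {
  se <- ratio_or_flag(cc$tp, cc$tp + cc$fn)
  sp <- ratio_or_flag(cc$tn, cc$tn + cc$fp)
  out <- (as.numeric(se) + as.numeric(sp)) / 2
  if (isTRUE(attr(se, "degenerate")) || isTRUE(attr(sp, "degenerate")))
    attr(out, "degenerate") <- TRUE
  out
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`; 0 with a `degenerate` attribute when no positives
#' were predicted.
#'
#' @param cc a `confusion_counts`.
#' @return Numeric in `[0, 1]`.
#' @export
precision <- function(cc) ratio_or_flag(cc$tp, cc$tp + cc$fp)

#' Sensitivity (recall)
#'
#' `TP / (TP + FN)`; 0 with a `degenerate` attribute when there are no
#' positives, as on normal scans.
#'
#' @param cc a `confusion_counts`.
#' @return Numeric in `[0, 1]`.
#' @export
sensitivity <- function(cc) ratio_or_flag(cc$tp, cc$tp + cc$fn)

#' F1 score
#'
#' Harmonic mean of precision and sensitivity,
#' `2 * P * S / (P + S)`.
#'
#' @param cc a `confusion_counts`.
#' @return Numeric in `[0, 1]`.
#' @export
f1_score <- function(cc) {
  p <- as.numeric(precision(cc))
  s <- as.numeric(sensitivity(cc))
  if (p + s == 0) return(structure(0, degenerate = TRUE))
  2 * p * s / (p + s)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank-sum probability that a random
#' positive scores above a random negative, with ties handled by
#' midranks.
#'
#' @param truth binary truth vector (see [confusion()]).
#' @param scores numeric scores, larger = more positive.
#' @return Numeric in `[0, 1]`; `NA` with a `degenerate` attribute when a
#'   class is absent.
#' @export
roc_auc <- function(truth, scores) {
  y <- as_binary01(truth)
  if (length(y) != length(scores)) stop("truth and scores lengths differ")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(structure(NA_real_, degenerate = TRUE))
  r <- rank(scores)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report from counts (and optionally scores)
#'
#' @param cc a `confusion_counts`.
#' @param truth,scores optional vectors for AUC.
#' @return A list with `balanced_accuracy`, `precision`, `sensitivity`,
#'   `f1`, optionally `auc`, and `degenerate_flags`.
#' @export
metric_report <- function(cc, truth = NULL, scores = NULL) {
  vals <- list(balanced_accuracy = balanced_accuracy(cc),
               precision = precision(cc),
               sensitivity = sensitivity(cc),
               f1 = f1_score(cc))
  if (!is.null(truth) && !is.null(scores))
    vals$auc <- roc_auc(truth, scores)
  flags <- vapply(vals, function(v) isTRUE(attr(v, "degenerate")), TRUE)
  vals <- lapply(vals, as.numeric)
  vals$degenerate_flags <- flags
  vals
}

#' Burden category of a scan
#'
#' Clinical CMB-burden bands: category 1 = 1-4 microbleeds, 2 = 5-9,
#' 3 = 10 or more. Scans with zero microbleeds are `"normal"`, reported
#' separately rather than folded into category 1.
#'
#' @param n_cmb microbleed count (>= 0).
#' @return `"normal"`, or integer 1, 2 or 3.
#' @export
categorize_scan <- function(n_cmb) {
  if (n_cmb < 0) stop("n_cmb must be nonnegative")
  if (n_cmb == 0) return("normal")
  if (n_cmb <= 4) 1L else if (n_cmb <= 9) 2L else 3L
}

#' Burden-stratified metric report
#'
#' Pools confusion counts within each burden category (micro-pooling),
#' then computes the metrics per category and overall. Empty categories
#' are omitted.
#'
#' @param per_scan data.frame with columns `scan_id`, `n_cmb`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @return Named list of [metric_report()] results for `overall`,
#'   `normal` and categories `cat1`-`cat3` present in the data, each with
#'   the pooled counts attached as `$counts`.
#' @export
stratified_report <- function(per_scan) {
  need <- c("scan_id", "n_cmb", "tp", "fp", "fn", "tn")
  if (!all(need %in% names(per_scan)))
    stop("per_scan needs columns ", paste(need, collapse = ","))
  cat_of <- vapply(per_scan$n_cmb,
                   function(n) as.character(categorize_scan(n)), "")
  pool <- function(rows) {
    cc <- confusion_counts(sum(rows$tp), sum(rows$fp), sum(rows$fn),
                           sum(rows$tn))
    rep_ <- metric_report(cc)
    rep_$counts <- cc
    rep_
  }
  out <- list(overall = pool(per_scan))
  for (lv in c("normal", "1", "2", "3")) {
    rows <- per_scan[cat_of == lv, , drop = FALSE]
    if (!nrow(rows)) next
    nm <- if (lv == "normal") "normal" else paste0("cat", lv)
    out[[nm]] <- pool(rows)
  }
  out
}

#' Build stratified cross-validation folds
#'
#' CMB patches are dealt round-robin after a seeded shuffle so per-fold
#' positive counts differ by at most one (TP-balanced folds); non-CMB
#' patches are split uniformly at random. With `group_by_scan`, whole
#' scans are assigned to folds (greedy balance on per-scan CMB count) so
#' no scan spans folds, mirroring a patient-level split.
#'
#' @param ps a `patch_set`.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @param group_by_scan keep all patches of a scan in one fold.
#' @return An object of class `cv_plan`: list with `k`, `seed`, `fold`
#'   (integer fold id per patch).
#' @export
make_folds <- function(ps, k = 5L, seed = 1L, group_by_scan = FALSE) {
  k <- as.integer(k)
  if (k < 2) stop("`k` must be >= 2")
  lab <- ps$meta$label
  n_cmb <- sum(lab == "cmb")
  if (n_cmb < k) stop("need at least k (", k, ") cmb patches, have ", n_cmb)
  fold <- integer(n_patches(ps))
  with_seed(seed, {
    if (group_by_scan) {
      scans <- unique(ps$meta$scan_id)
      scans <- sample(scans)
      npos <- vapply(scans, function(s)
        sum(lab == "cmb" & ps$meta$scan_id == s), 1L)
      ord <- order(-npos)
      load <- numeric(k)
      assign_fold <- setNames(integer(length(scans)), scans)
      for (i in ord) {
        f <- which.min(load)
        assign_fold[scans[i]] <- f
        load[f] <- load[f] + npos[i] + 1e-3  # tie-break by total size
      }
      fold <- assign_fold[ps$meta$scan_id]
    } else {
      pos <- sample(which(lab == "cmb"))
      neg <- sample(which(lab != "cmb"))
      fold[pos] <- rep_len(seq_len(k), length(pos))
      fold[neg] <- rep_len(seq_len(k), length(neg))
    }
  })
  structure(list(k = k, seed = as.integer(seed),
                 group_by_scan = group_by_scan,
                 fold = as.integer(fold)),
            class = "cv_plan")
}

#' Run repeated stratified k-fold cross-validation
#'
#' Five-times five-fold by default: repeat r builds folds with seed
#' `seed + r`, fits on k-1 folds and scores the held-out fold. Hard
#' labels use threshold 0.5 on the returned P(cmb).
#'
#' @param ps a `patch_set`.
#' @param train_fn callback `function(train_ps, seed)` returning a model.
#' @param predict_fn callback `function(model, test_ps)` returning P(cmb).
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed base seed.
#' @param group_by_scan passed to [make_folds()].
#' @return An object of class `cmb_cv`: data.frame `cells` with one row
#'   per (repeat, fold) carrying confusion counts and metrics.
#' @export
run_repeated_cv <- function(ps, train_fn, predict_fn, k = 5L,
                            repeats = 5L, seed = 1L,
                            group_by_scan = FALSE) {
  cells <- list()
  for (r in seq_len(repeats)) {
    plan <- make_folds(ps, k, seed + r, group_by_scan)
    for (f in seq_len(k)) {
      test_idx <- which(plan$fold == f)
      train_idx <- which(plan$fold != f)
      cell_id <- sprintf("repeat %d fold %d", r, f)
      res <- tryCatch({
        fit <- train_fn(subset_patches(ps, train_idx), seed + r)
        scores <- predict_fn(fit, subset_patches(ps, test_idx))
        truth <- as.integer(ps$meta$label[test_idx] == "cmb")
        cc <- confusion(truth, as.integer(scores > 0.5))
        auc <- roc_auc(truth, scores)
        data.frame(repeat_ = r, fold = f, tp = cc$tp, fp = cc$fp,
                   fn = cc$fn, tn = cc$tn,
                   balanced_accuracy = as.numeric(balanced_accuracy(cc)),
                   auc = as.numeric(auc),
                   precision = as.numeric(precision(cc)),
                   sensitivity = as.numeric(sensitivity(cc)),
                   f1 = as.numeric(f1_score(cc)))
      }, error = function(e)
        stop("cross-validation aborted at ", cell_id, ": ",
             conditionMessage(e)))
      cells[[length(cells) + 1]] <- res
    }
  }
  structure(list(cells = do.call(rbind, cells), k = k, repeats = repeats,
                 seed = seed),
            class = "cmb_cv")
}

#' Aggregate repeated cross-validation results
#'
#' Each repeat is first averaged over its folds; the returned `mean` and
#' `sd` are the arithmetic mean and the sample standard deviation
#' (n - 1 divisor) of those per-repeat values.
#'
#' @param result a `cmb_cv` from [run_repeated_cv()], or a data.frame
#'   shaped like its `cells` element.
#' @return A list with `per_repeat` (data.frame), `mean` and `sd`
#'   (named numeric vectors; `sd` is `NULL` with a single repeat).
#' @export
aggregate_cv <- function(result) {
  cells <- if (inherits(result, "cmb_cv")) result$cells else result
  metric_cols <- setdiff(names(cells), c("repeat_", "fold"))
  reps <- sort(unique(cells$repeat_))
  per_repeat <- do.call(rbind, lapply(reps, function(r) {
    rows <- cells[cells$repeat_ == r, metric_cols, drop = FALSE]
    cbind(data.frame(repeat_ = r), as.data.frame(t(colMeans(rows))))
  }))
  m <- colMeans(per_repeat[metric_cols])
  s <- if (length(reps) >= 2) apply(per_repeat[metric_cols], 2, stats::sd)
       else NULL
  list(per_repeat = per_repeat, mean = m, sd = s)
}
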