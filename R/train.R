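#' Training control parameters
#'
#' Defaults follow the production recipe: Adam with learning rate 0.01 and
#' weight decay 1e-4 (L2 added to the gradient), cross-entropy over two
#' classes, 200 epochs, batches of 128.
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (capped at the set size).
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @param bn_momentum running-statistics momentum for batch norm.
#' @param early_stop_train_acc optional training-accuracy level at which
#'   to stop early (e.g. 1 on separable data).
#' @param verbose print a line per epoch.
#' @return An object of class `cmb_control`.
#' @export
cmb_control <- function(lr = 0.01, weight_decay = 1e-4, epochs = 200L,
                        batch_size = 128L, seed = 1L, bn_momentum = 0.1,
                        early_stop_train_acc = NULL, verbose = FALSE) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), bn_momentum = bn_momentum,
                 early_stop_train_acc = early_stop_train_acc,
                 verbose = isTRUE(verbose)),
            class = "cmb_control")
}

softmax_cols <- function(L) {
  m <- apply(L, 2, max)
  P <- exp(sweep(L, 2, m))
  sweep(P, 2, colSums(P), "/")
}

#' Fit the patch classifier
#'
#' Trains the 3D CNN on a labelled patch set with Adam and two-class
#' cross-entropy. When a validation set is supplied, the returned weights
#' are those of the epoch with the best validation balanced accuracy
#' (ties favour the earlier epoch); otherwise the final weights are kept.
#' Passing a previously fitted `cmb_net` as `init` continues training
#' from its weights (pretrain/fine-tune workflow); no layers are frozen.
#'
#' @param x a `patch_set` containing both classes.
#' @param val optional validation `patch_set` for model selection.
#' @param model a [cmb_model()]; its edge must match the patches.
#' @param control a [cmb_control()].
#' @param init optional `cmb_net` whose weights initialise training.
#' @return An object of class `cmb_net` with elements `params`, `state`
#'   (batch-norm buffers), `model`, `control`, `history` (per-epoch loss
#'   and accuracy), `best_epoch`.
#' @export
cmb_train <- function(x, val = NULL, model = cmb_model(edge = x$edge),
                      control = cmb_control(), init = NULL) {
  stopifnot(inherits(x, "patch_set"))
  if (model$edge != x$edge)
    stop("model edge (", model$edge, ") does not match patch edge (",
         x$edge, ")")
  y <- as.integer(x$meta$label == "cmb")
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  n <- length(y)
  bs <- min(control$batch_size, n)
  if (!is.null(init)) {
    stopifnot(inherits(init, "cmb_net"))
    params <- init$params
    state <- init$state
  } else {
    pw <- init_params(model, control$seed)
    params <- pw$params
    state <- pw$state
  }
  opt_m <- lapply(params, function(p) p * 0)
  opt_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  hist_rows <- vector("list", control$epochs)
  best <- list(metric = -Inf, epoch = NA_integer_,
               params = params, state = state)
  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- x$x[, idx, drop = FALSE]
        yb <- y[idx]
        fw <- net_forward(model, params, state, Xb, training = TRUE,
                          bn_momentum = control$bn_momentum)
        state <- fw$state
        P <- softmax_cols(fw$logits)
        picked <- P[cbind(yb + 1L, seq_along(yb))]
        ep_loss <- ep_loss - sum(log(pmax(picked, 1e-12)))
        ep_correct <- ep_correct +
          sum((P[2, ] > 0.5) == (yb == 1L))
        dL <- P
        dL[cbind(yb + 1L, seq_along(yb))] <-
          dL[cbind(yb + 1L, seq_along(yb))] - 1
        dL <- dL / length(yb)
        grads <- net_backward(model, params, fw$caches, dL)
        step <- step + 1L
        for (nm in names(params)) {
          g <- grads[[nm]] + control$weight_decay * params[[nm]]
          opt_m[[nm]] <- b1 * opt_m[[nm]] + (1 - b1) * g
          opt_v[[nm]] <- b2 * opt_v[[nm]] + (1 - b2) * g * g
          mhat <- opt_m[[nm]] / (1 - b1^step)
          vhat <- opt_v[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] -
            control$lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      train_loss <- ep_loss / n
      train_acc <- ep_correct / n
      val_bacc <- NA_real_
      if (!is.null(val)) {
        vp <- predict_probs(model, params, state, val$x)
        vy <- as.integer(val$meta$label == "cmb")
        cc <- confusion(vy, as.integer(vp > 0.5))
        val_bacc <- balanced_accuracy(cc)
        if (val_bacc > best$metric) {
          best <- list(metric = val_bacc, epoch = epoch,
                       params = params, state = state)
        }
      }
      hist_rows[[epoch]] <- data.frame(epoch = epoch, loss = train_loss,
                                       train_acc = train_acc,
                                       val_bacc = val_bacc)
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val bacc %s",
                        epoch, train_loss, train_acc,
                        ifelse(is.na(val_bacc), "-",
                               sprintf("%.3f", val_bacc))))
      if (!is.finite(train_loss))
        stop("training loss diverged at epoch ", epoch)
      if (!is.null(control$early_stop_train_acc) &&
          train_acc >= control$early_stop_train_acc) break
    }
  })
  history <- do.call(rbind, Filter(Negate(is.null), hist_rows))
  if (!is.null(val) && is.finite(best$metric)) {
    params <- best$params
    state <- best$state
    best_epoch <- best$epoch
  } else best_epoch <- nrow(history)
  structure(list(params = params, state = state, model = model,
                 control = control, history = history,
                 best_epoch = best_epoch,
                 classes = c("non_cmb", "cmb")),
            class = "cmb_net")
}

predict_probs <- function(model, params, state, X, chunk = 256L) {
  n <- ncol(X)
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- net_forward(model, params, state, X[, idx, drop = FALSE],
                      training = FALSE)
    out[idx] <- softmax_cols(fw$logits)[2, ]
  }
  out
}

#' Predict class probabilities or labels for patches
#'
#' @param object a fitted `cmb_net`.
#' @param newdata a `patch_set` (or bare `edge^3 x n` matrix).
#' @param type `"prob"` for P(cmb), `"class"` for hard labels at
#'   threshold 0.5.
#' @param ... unused.
#' @return Numeric vector of probabilities or character label vector.
#' @export
predict.cmb_net <- function(object, newdata,
                            type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "patch_set")) newdata$x else as.matrix(newdata)
  if (nrow(X) != object$model$edge^3)
    stop("patch edge does not match the fitted model input")
  p <- predict_probs(object$model, object$params, object$state, X)
  if (type == "prob") p else ifelse(p > 0.5, "cmb", "non_cmb")
}

#' @export
print.cmb_net <- function(x, ...) {
  cat("<cmb_net> fitted patch classifier\n")
  cat(" ", paste(architecture_audit(x), collapse = " | "), "\n")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs run, final loss %.4f, train accuracy %.3f\n",
              nrow(x$history), h$loss, h$train_acc))
  if (!is.na(h$val_bacc))
    cat(sprintf("  kept epoch %d (validation balanced accuracy %.3f)\n",
                x$best_epoch, max(x$history$val_bacc, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cmb_net <- function(object, ...) {
  cat("Patch classifier:", count_parameters(object), "parameters\n")
  cat("Layers:\n")
  cat(paste0("  ", architecture_audit(object), collapse = "\n"), "\n")
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.cmb_net <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss")
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy")
  if (any(!is.na(h$val_bacc)))
    graphics::lines(h$epoch, h$val_bacc, lty = 2)
  invisible(x)
}

#' @export
coef.cmb_net <- function(object, ...) object$params

#' Augmentation configuration
#'
#' @param transforms subset of `flip_vertical`, `flip_horizontal`,
#'   `rescale`, `intensity_shift`.
#' @param copies_per_sample stochastic copies appended per source patch.
#' @param seed RNG seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(transforms = c("flip_vertical",
                                          "flip_horizontal",
                                          "rescale", "intensity_shift"),
                           copies_per_sample = 1L, seed = 1L) {
  known <- c("flip_vertical", "flip_horizontal", "rescale",
             "intensity_shift")
  bad <- setdiff(transforms, known)
  if (length(bad)) stop("unknown transform: ", paste(bad, collapse = ", "))
  structure(list(transforms = transforms,
                 copies_per_sample = as.integer(copies_per_sample),
                 seed = as.integer(seed)),
            class = "augment_config")
}

flip_index <- function(edge, axis) {
  id <- array(seq_len(edge^3), dim = rep(edge, 3))
  rev_ <- edge:1
  as.vector(switch(axis, id[rev_, , ], id[, rev_, ], id[, , rev_]))
}

flip_patch <- function(xcol, edge, axis) xcol[flip_index(edge, axis)]

#' Augment a patch set
#'
#' Appends `copies_per_sample` stochastically transformed copies of every
#' patch: each enabled flip is applied with probability 1/2
#' (horizontal = left-right axis, vertical = anterior-posterior axis),
#' `rescale` multiplies intensities by a factor in [0.9, 1.1] and
#' `intensity_shift` adds an offset in [-0.1, 0.1] (standardised scale).
#' Labels are preserved; new patches carry provenance `augmented`.
#'
#' @param ps a nonempty `patch_set`.
#' @param config an [augment_config()].
#' @return A `patch_set` with originals followed by augmented copies.
#' @export
augment_set <- function(ps, config = augment_config()) {
  if (n_patches(ps) == 0) stop("cannot augment an empty patch set")
  e <- ps$edge
  fidx <- list(h = flip_index(e, 1L), v = flip_index(e, 2L))
  n <- n_patches(ps)
  copies <- config$copies_per_sample
  newx <- matrix(0, nrow = e^3, ncol = n * copies)
  with_seed(config$seed, {
    for (cpy in seq_len(copies)) {
      for (i in seq_len(n)) {
        v <- ps$x[, i]
        if ("flip_horizontal" %in% config$transforms &&
            stats::runif(1) < 0.5) v <- v[fidx$h]
        if ("flip_vertical" %in% config$transforms &&
            stats::runif(1) < 0.5) v <- v[fidx$v]
        if ("rescale" %in% config$transforms)
          v <- v * stats::runif(1, 0.9, 1.1)
        if ("intensity_shift" %in% config$transforms)
          v <- v + stats::runif(1, -0.1, 0.1)
        newx[, (cpy - 1L) * n + i] <- v
      }
    }
  })
  meta <- ps$meta[rep(seq_len(n), copies), , drop = FALSE]
  meta$provenance <- "augmented"
  rownames(meta) <- NULL
  bind_patches(ps, patch_set(newx, meta, e))
}
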