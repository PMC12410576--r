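# 3D CNN for 11x11x11 patch classification. Two Conv+BN+ReLU layers per
# stage (32, 64, 128 filters, 3x3x3 kernels, same-padding), each stage
# closed by 2x2x2 max pooling and dropout (0.3/0.3/0.4), then Linear 256,
# dropout 0.4 and a 2-unit output. With same-padding only pooling shrinks
# the grid: 11 -> 5 -> 2 -> 1, so the flattened width equals the last
# filter count.

BN_EPS <- 1e-5

make_nb <- function(e) {
  coords <- expand.grid(ix = 0:(e - 1), iy = 0:(e - 1), iz = 0:(e - 1))
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- matrix(-1L, nrow = e^3, ncol = 27)
  for (t in 1:27) {
    jx <- coords$ix + offs$dx[t]
    jy <- coords$iy + offs$dy[t]
    jz <- coords$iz + offs$dz[t]
    ok <- jx >= 0 & jx < e & jy >= 0 & jy < e & jz >= 0 & jz < e
    nb[ok, t] <- as.integer(jx[ok] + e * jy[ok] + e^2 * jz[ok])
  }
  nb
}

make_pmap <- function(e) {
  o <- e %/% 2L
  grid <- expand.grid(ox = 0:(o - 1), oy = 0:(o - 1), oz = 0:(o - 1))
  offs <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  pmap <- matrix(-1L, nrow = o^3, ncol = 8)
  for (t in 1:8) {
    jx <- 2L * grid$ox + offs$a[t]
    jy <- 2L * grid$oy + offs$b[t]
    jz <- 2L * grid$oz + offs$c[t]
    ok <- jx < e & jy < e & jz < e
    pmap[ok, t] <- as.integer(jx[ok] + e * jy[ok] + e^2 * jz[ok])
  }
  pmap
}

#' Define the patch classifier architecture
#'
#' The default schedule is the production architecture: three stages of
#' two Conv+BN+ReLU layers (32, 64 and 128 filters of 3x3x3, padding 1),
#' each followed by 2x2x2 max pooling and dropout, then a 256-unit linear
#' layer, dropout, and a 2-unit output. Smaller schedules can be set for
#' reduced-scale experiments.
#'
#' @param conv_blocks list of `(filters, conv layers per stage)` pairs.
#' @param dropout per-stage dropout rates, one per block, in `[0, 1)`.
#' @param head_width hidden width of the fully connected head.
#' @param head_dropout dropout rate before the output layer.
#' @param edge input patch edge (voxels); must survive one floor-halving
#'   per stage.
#' @return An object of class `cmb_model` holding the layer plan and
#'   precomputed geometry tables.
#' @export
cmb_model <- function(conv_blocks = list(c(32, 2), c(64, 2), c(128, 2)),
                      dropout = c(0.3, 0.3, 0.4),
                      head_width = 256L, head_dropout = 0.4,
                      edge = 11L) {
  edge <- as.integer(edge)
  if (length(dropout) != length(conv_blocks))
    stop("need one dropout rate per conv block")
  if (any(dropout < 0 | dropout >= 1) || head_dropout < 0 || head_dropout >= 1)
    stop("dropout rates must lie in [0, 1)")
  plan <- list()
  nb_tabs <- list()
  pmaps <- list()
  e <- edge
  cin <- 1L
  for (s in seq_along(conv_blocks)) {
    filt <- as.integer(conv_blocks[[s]][1])
    reps <- as.integer(conv_blocks[[s]][2])
    if (e < 2L)
      stop("input edge ", edge, " is too small for ", length(conv_blocks),
           " pooling stages")
    key <- as.character(e)
    if (is.null(nb_tabs[[key]])) nb_tabs[[key]] <- make_nb(e)
    for (r in seq_len(reps)) {
      nm <- sprintf("conv%d_%d", s, r)
      plan[[length(plan) + 1]] <- list(type = "conv", name = nm,
                                       Cin = cin, Cout = filt, nb = key)
      plan[[length(plan) + 1]] <- list(type = "bn", name = nm,
                                       C = filt, V = e^3)
      plan[[length(plan) + 1]] <- list(type = "relu")
      cin <- filt
    }
    if (is.null(pmaps[[key]])) pmaps[[key]] <- make_pmap(e)
    plan[[length(plan) + 1]] <- list(type = "pool", C = filt, key = key,
                                     Vin = e^3, Vout = (e %/% 2L)^3)
    e <- e %/% 2L
    plan[[length(plan) + 1]] <- list(type = "dropout", rate = dropout[s])
  }
  flat <- cin * e^3
  plan[[length(plan) + 1]] <- list(type = "linear", name = "fc1",
                                   d_in = flat, d_out = as.integer(head_width))
  plan[[length(plan) + 1]] <- list(type = "relu")
  plan[[length(plan) + 1]] <- list(type = "dropout", rate = head_dropout)
  plan[[length(plan) + 1]] <- list(type = "linear", name = "fc2",
                                   d_in = as.integer(head_width), d_out = 2L)
  structure(list(conv_blocks = conv_blocks, dropout = dropout,
                 head_width = as.integer(head_width),
                 head_dropout = head_dropout, edge = edge,
                 plan = plan, nb = nb_tabs, pmap = pmaps,
                 spatial = spatial_schedule(edge, length(conv_blocks))),
            class = "cmb_model")
}

#' Spatial size after each pooling stage
#'
#' Floor-halving schedule of the cubic grid edge, e.g. 11 -> 5 -> 2 -> 1.
#'
#' @param edge input edge length.
#' @param n_stages number of pooling stages.
#' @return Integer vector of length `n_stages + 1` starting at `edge`.
#' @export
spatial_schedule <- function(edge, n_stages = 3L) {
  out <- as.integer(edge)
  for (s in seq_len(n_stages)) out <- c(out, out[length(out)] %/% 2L)
  out
}

#' @export
print.cmb_model <- function(x, ...) {
  cat("<cmb_model>", paste(architecture_audit(x), collapse = " | "), "\n")
  cat("spatial schedule:", paste(x$spatial, collapse = " -> "),
      "| parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Human-readable layer sequence
#'
#' One string per layer in forward order, e.g. `"Conv+BN+ReLU 32x3x3x3"`,
#' `"MaxPool 2x2x2"`, `"Dropout 0.3"`, `"Linear 256"`, `"Linear 2"`.
#'
#' @param model a `cmb_model` or `cmb_net`.
#' @return Character vector.
#' @export
architecture_audit <- function(model) {
  if (inherits(model, "cmb_net")) model <- model$model
  out <- character(0)
  i <- 1
  plan <- model$plan
  while (i <= length(plan)) {
    ly <- plan[[i]]
    if (ly$type == "conv") {
      out <- c(out, sprintf("Conv+BN+ReLU %dx3x3x3", ly$Cout))
      i <- i + 3  # conv, bn, relu emitted as one line
    } else if (ly$type == "pool") {
      out <- c(out, "MaxPool 2x2x2"); i <- i + 1
    } else if (ly$type == "dropout") {
      out <- c(out, sprintf("Dropout %.1f", ly$rate)); i <- i + 1
    } else if (ly$type == "linear") {
      out <- c(out, sprintf("Linear %d", ly$d_out)); i <- i + 1
    } else i <- i + 1
  }
  out
}

init_params <- function(model, seed) {
  params <- list()
  state <- list()
  with_seed(seed, {
    for (ly in model$plan) {
      if (ly$type == "conv") {
        fan_in <- ly$Cin * 27
        params[[paste0(ly$name, "_W")]] <-
          matrix(stats::rnorm(ly$Cout * fan_in, 0, sqrt(2 / fan_in)),
                 nrow = ly$Cout)
        params[[paste0(ly$name, "_b")]] <- numeric(ly$Cout)
      } else if (ly$type == "bn") {
        params[[paste0(ly$name, "_gamma")]] <- rep(1, ly$C)
        params[[paste0(ly$name, "_beta")]] <- numeric(ly$C)
        state[[paste0(ly$name, "_rm")]] <- numeric(ly$C)
        state[[paste0(ly$name, "_rv")]] <- rep(1, ly$C)
      } else if (ly$type == "linear") {
        params[[paste0(ly$name, "_W")]] <-
          matrix(stats::rnorm(ly$d_out * ly$d_in, 0, sqrt(2 / ly$d_in)),
                 nrow = ly$d_out)
        params[[paste0(ly$name, "_b")]] <- numeric(ly$d_out)
      }
    }
  })
  list(params = params, state = state)
}

#' Count trainable parameters
#'
#' Sums convolution and linear weights/biases and batch-norm scale/shift
#' parameters (running statistics are buffers, not parameters).
#'
#' @param model a `cmb_model` or `cmb_net`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "cmb_net"))
    return(sum(vapply(model$params, length, 1L)))
  total <- 0L
  for (ly in model$plan) {
    total <- total + switch(ly$type,
      conv = ly$Cout * ly$Cin * 27L + ly$Cout,
      bn = 2L * ly$C,
      linear = ly$d_out * ly$d_in + ly$d_out,
      0L)
  }
  total
}

channel_sum <- function(M, V, C) {
  .colSums(matrix(.rowSums(M, nrow(M), ncol(M)), V, C), V, C)
}

expand_c <- function(v, V) rep(v, each = V)

# Forward pass. X is (features x batch). Returns logits and, when
# `training`, a cache list for the backward pass. Dropout masks are drawn
# from the R RNG of the caller.
net_forward <- function(model, params, state, X, training = FALSE,
                        bn_momentum = 0.1) {
  caches <- vector("list", length(model$plan))
  for (i in seq_along(model$plan)) {
    ly <- model$plan[[i]]
    if (ly$type == "conv") {
      if (training) caches[[i]] <- list(X = X)
      X <- .conv3d_fwd(X, params[[paste0(ly$name, "_W")]],
                       params[[paste0(ly$name, "_b")]],
                       model$nb[[ly$nb]], ly$Cin)
    } else if (ly$type == "bn") {
      g <- params[[paste0(ly$name, "_gamma")]]
      be <- params[[paste0(ly$name, "_beta")]]
      V <- ly$V; C <- ly$C
      if (training) {
        N <- V * ncol(X)
        mu <- channel_sum(X, V, C) / N
        Xc <- X - expand_c(mu, V)
        va <- channel_sum(Xc * Xc, V, C) / N
        invstd <- 1 / sqrt(va + BN_EPS)
        xhat <- Xc * expand_c(invstd, V)
        caches[[i]] <- list(xhat = xhat, invstd = invstd, gamma = g)
        ub <- if (N > 1) N / (N - 1) else 1
        state[[paste0(ly$name, "_rm")]] <-
          (1 - bn_momentum) * state[[paste0(ly$name, "_rm")]] + bn_momentum * mu
        state[[paste0(ly$name, "_rv")]] <-
          (1 - bn_momentum) * state[[paste0(ly$name, "_rv")]] +
          bn_momentum * va * ub
        X <- xhat * expand_c(g, V) + expand_c(be, V)
      } else {
        rm_ <- state[[paste0(ly$name, "_rm")]]
        rv_ <- state[[paste0(ly$name, "_rv")]]
        X <- (X - expand_c(rm_, V)) *
          expand_c(g / sqrt(rv_ + BN_EPS), V) + expand_c(be, V)
      }
    } else if (ly$type == "relu") {
      mask <- X > 0
      if (training) caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (ly$type == "pool") {
      res <- .maxpool_fwd(X, model$pmap[[ly$key]], ly$C, ly$Vin)
      if (training) caches[[i]] <- list(amax = res$amax)
      X <- res$Y
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (matrix(stats::runif(length(X)), nrow(X)) >= ly$rate) /
          (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      }
    } else if (ly$type == "linear") {
      if (training) caches[[i]] <- list(X = X)
      X <- params[[paste0(ly$name, "_W")]] %*% X +
        params[[paste0(ly$name, "_b")]]
    }
  }
  list(logits = X, caches = caches, state = state)
}

# Backward pass from d(logits); returns gradients named like params.
net_backward <- function(model, params, caches, dY) {
  grads <- list()
  for (i in rev(seq_along(model$plan))) {
    ly <- model$plan[[i]]
    cache <- caches[[i]]
    if (ly$type == "linear") {
      W <- params[[paste0(ly$name, "_W")]]
      grads[[paste0(ly$name, "_W")]] <- dY %*% t(cache$X)
      grads[[paste0(ly$name, "_b")]] <- .rowSums(dY, nrow(dY), ncol(dY))
      dY <- crossprod(W, dY)
    } else if (ly$type == "dropout") {
      if (!is.null(cache)) dY <- dY * cache$mask
    } else if (ly$type == "pool") {
      dY <- .maxpool_bwd(dY, cache$amax, ly$C, ly$Vin)
    } else if (ly$type == "relu") {
      dY <- dY * cache$mask
    } else if (ly$type == "bn") {
      V <- ly$V; C <- ly$C
      N <- V * ncol(dY)
      xhat <- cache$xhat
      grads[[paste0(ly$name, "_gamma")]] <- channel_sum(dY * xhat, V, C)
      grads[[paste0(ly$name, "_beta")]] <- channel_sum(dY, V, C)
      dxhat <- dY * expand_c(cache$gamma, V)
      m1 <- channel_sum(dxhat, V, C) / N
      m2 <- channel_sum(dxhat * xhat, V, C) / N
      dY <- expand_c(cache$invstd, V) *
        (dxhat - expand_c(m1, V) - xhat * expand_c(m2, V))
    } else if (ly$type == "conv") {
      res <- .conv3d_bwd(cache$X, params[[paste0(ly$name, "_W")]], dY,
                         model$nb[[ly$nb]], ly$Cin)
      grads[[paste0(ly$name, "_W")]] <- res$dW
      grads[[paste0(ly$name, "_b")]] <- as.numeric(res$db)
      dY <- res$dX
    }
  }
  grads
}
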