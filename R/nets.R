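# Single-layer convolutional response-prediction networks:
# conv -> ReLU -> max-pool -> fully-connected linear scalar readout.
# Variants: cnn4 / cnn9 learn their kernels from scratch; "fixed" variants
# freeze the first layer to a kernel bank (sparse-code, Gabor, Gabor+LOG)
# and learn only the readout. Training is Adam on mean squared error with
# early stopping on validation Pearson.

#' Network configuration
#'
#' @param variant `"cnn4"`, `"cnn9"`, or `"fixed"`.
#' @param front_end A `kernel_bank` for the frozen first layer (required
#'   for `"fixed"`).
#' @param n_kernels Number of learned first-layer kernels (4 or 9 for the
#'   learned variants; ignored for `"fixed"`).
#' @param kernel_size Odd conv kernel side (default 9).
#' @param input_side Stimulus side (default 20).
#' @param pool_window,pool_stride Max-pooling geometry over the conv map
#'   (defaults 3 and 3: disjoint windows pooling the default 12 x 12 map to
#'   4 x 4, which preserves coarse RF position while keeping the readout
#'   small).
#' @param seed Integer seed for weight initialization and batching.
#' @return A `net_config`.
#' @export
net_config <- function(variant = c("cnn4", "cnn9", "fixed"), front_end = NULL,
                       n_kernels = NULL, kernel_size = 9, input_side = 20,
                       pool_window = 3, pool_stride = 3, seed = 1) {
  variant <- match.arg(variant)
  kernel_size <- check_odd_size(kernel_size)
  if (variant == "fixed") {
    if (is.null(front_end) || !inherits(front_end, "kernel_bank")) {
      stop_invalid("fixed variant requires a kernel_bank front_end")
    }
    if (kernel_side(front_end) != kernel_size) {
      stop_invalid("front_end kernel side must equal kernel_size")
    }
    n_kernels <- length(front_end)
  } else {
    if (is.null(n_kernels)) n_kernels <- if (variant == "cnn4") 4L else 9L
  }
  conv_side <- input_side - kernel_size + 1L
  pooled_side <- (conv_side - pool_window) / pool_stride + 1
  if (pooled_side < 1 || pooled_side %% 1 != 0) {
    stop_invalid("pooling geometry infeasible: conv map ", conv_side, "x",
                 conv_side, " with window ", pool_window, " stride ",
                 pool_stride, " gives pooled side ", pooled_side)
  }
  structure(list(variant = variant, n_kernels = as.integer(n_kernels),
                 kernel_size = kernel_size, input_side = as.integer(input_side),
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride),
                 conv_side = as.integer(conv_side),
                 pooled_side = as.integer(pooled_side),
                 front_end = front_end, seed = seed),
            class = "net_config")
}

#' Build an (untrained) response-prediction network
#'
#' Architecture: valid convolution (`input_side - kernel_size + 1` maps),
#' ReLU, max pooling, and a fully connected linear scalar output. Fixed
#' variants copy the front-end bank into the frozen conv layer (no conv
#' bias; the bank is the feature basis as-is).
#'
#' @param config A `net_config`.
#' @return An `rf_net` with freshly initialized weights.
#' @export
build_network <- function(config) {
  C <- config$n_kernels
  k2 <- config$kernel_size^2
  np <- config$pooled_side^2
  frozen <- config$variant == "fixed"
  with_seed(config$seed, {
    W <- if (frozen) {
      bank_matrix(config$front_end)
    } else {
      matrix(stats::rnorm(k2 * C, sd = sqrt(2 / k2)), k2, C)
    }
    conv_bias <- if (frozen) NULL else numeric(C)
    fc_w <- matrix(stats::rnorm(np * C, sd = sqrt(1 / (np * C))), np * C, 1)
    fc_b <- 0
    structure(list(config = config, W = W, conv_bias = conv_bias,
                   fc_w = fc_w, fc_b = fc_b,
                   first_layer_frozen = frozen,
                   history = NULL, epochs_to_stop = NA_integer_),
              class = "rf_net")
  })
}

#' Count learnable parameters of a network
#'
#' Trainable scalars only: the frozen first layer of fixed variants
#' contributes nothing.
#'
#' @param net An `rf_net`.
#' @return Integer count.
#' @examples
#' count_learnable_params(build_network(net_config("cnn4")))
#' @export
count_learnable_params <- function(net) {
  cfg <- net$config
  conv <- if (net$first_layer_frozen) 0L else cfg$n_kernels * (cfg$kernel_size^2 + 1L)
  conv + length(net$fc_w) + 1L
}

# Pooling geometry: win_pos is an np x pw^2 matrix of conv-map positions
# (pooled positions in rows, within-window offsets in columns, both
# column-major), and cols[[k]] indexes the (position, channel) columns of
# the n x (n_conv*C) response matrix for within-window offset k.
pool_geometry <- function(cfg) {
  cs <- cfg$conv_side
  ps <- cfg$pooled_side
  pw <- cfg$pool_window
  np <- ps * ps
  win_pos <- matrix(0L, np, pw * pw)
  i <- 1L
  for (pc in seq_len(ps)) {
    for (pr in seq_len(ps)) {
      r0 <- (pr - 1L) * cfg$pool_stride
      c0 <- (pc - 1L) * cfg$pool_stride
      win_pos[i, ] <- as.integer(outer(r0 + seq_len(pw), (c0 + seq_len(pw) - 1L) * cs, "+"))
      i <- i + 1L
    }
  }
  n_conv <- cs * cs
  cols <- lapply(seq_len(pw * pw), function(k) {
    as.integer(outer(win_pos[, k], (seq_len(cfg$n_kernels) - 1L) * n_conv, "+"))
  })
  list(win_pos = win_pos, cols = cols)
}

# Forward pass on a cached im2col matrix. Returns pooled features
# (n x np*C, pooled position fastest within channel) and, if want_argmax,
# the within-window offset of each pooled max for backpropagation.
net_forward <- function(net, Pm2, n, want_argmax = FALSE) {
  cfg <- net$config
  V <- Pm2 %*% net$W                            # (n * n_conv) x C
  if (!is.null(net$conv_bias)) V <- sweep(V, 2, net$conv_bias, "+")
  V[V < 0] <- 0
  n_conv <- cfg$conv_side^2
  C <- cfg$n_kernels
  M <- V
  dim(M) <- c(n, n_conv * C)
  pg <- pool_geometry(cfg)
  pooled <- M[, pg$cols[[1]], drop = FALSE]
  karg <- if (want_argmax) matrix(1L, n, ncol(pooled)) else NULL
  for (k in seq_along(pg$cols)[-1]) {
    cand <- M[, pg$cols[[k]], drop = FALSE]
    sel <- cand > pooled                        # ties keep the first offset
    pooled[sel] <- cand[sel]
    if (want_argmax) karg[sel] <- k
  }
  pred <- as.numeric(pooled %*% net$fc_w) + net$fc_b
  list(pred = pred, pooled = pooled, karg = karg, win_pos = pg$win_pos, V = V)
}

net_im2col <- function(net, X) {
  cfg <- net$config
  op <- make_conv_op(cfg$input_side, cfg$input_side, cfg$kernel_size)
  Pm2 <- as.matrix(X %*% op$St)
  dim(Pm2) <- c(nrow(X) * op$n_pos, op$k2)
  Pm2
}

#' Train a network
#'
#' Minimizes mean squared prediction error by Adam (learning rate `lr`,
#' minibatches of `batch`), early-stopping on validation Pearson with the
#' given `patience`; the weights at the best validation epoch are kept and
#' `epochs_to_stop` records that epoch. Frozen first layers receive no
#' gradient and are bit-identical before and after training. Deterministic
#' given the config seed.
#'
#' @param net An `rf_net` from [build_network()].
#' @param stimuli Training + validation `stimulus_set`.
#' @param y Response vector (training split must have nonzero variance).
#' @param split Fractions `c(train, val)` summing to <= 1 (default
#'   `c(0.8, 0.2)`), applied to a seeded shuffle; or a list with integer
#'   index vectors `train` and `val`.
#' @param lr Adam learning rate (default 1e-3).
#' @param batch Minibatch size (default 64).
#' @param max_epochs Epoch cap (default 300).
#' @param patience Early-stopping patience in epochs (default 15).
#' @return The trained `rf_net`, with a `history` tibble (epoch, train MSE,
#'   validation Pearson) and `epochs_to_stop`.
#' @export
train_network <- function(net, stimuli, y, split = c(0.8, 0.2), lr = 1e-3,
                          batch = 64, max_epochs = 300, patience = 15) {
  n <- length(stimuli)
  if (length(y) != n) stop_invalid("y must have one response per stimulus")
  cfg <- net$config
  if (stimulus_side(stimuli) != cfg$input_side) {
    stop_invalid("stimulus side does not match the network input side")
  }
  if (is.list(split)) {
    tr <- split$train; va <- split$val
  } else {
    if (length(split) != 2L || sum(split) > 1 + 1e-9 || any(split <= 0)) {
      stop_invalid("split must be two positive fractions summing to <= 1")
    }
    idx <- with_seed(cfg$seed, sample.int(n))
    n_tr <- floor(split[1] * n)
    n_va <- min(n - n_tr, ceiling(split[2] * n))
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
  }
  if (length(tr) < 2 || length(va) < 2) stop_invalid("degenerate split")
  if (stats::sd(y[tr]) == 0) {
    stop(errorCondition("training responses are constant",
                        class = c("rfpursuit_degenerate_target", "error")))
  }
  X <- stimulus_matrix(stimuli)
  op <- make_conv_op(cfg$input_side, cfg$input_side, cfg$kernel_size)
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]; yva <- y[va]
  n_tr <- length(tr)
  n_conv <- cfg$conv_side^2
  frozen <- net$first_layer_frozen
  if (frozen) {
    # the frozen front end makes the pooled features constant: compute them
    # once and train only the readout on them
    Ftr <- net_forward(net, net_im2col(net, Xtr), n_tr)$pooled
    Fva <- net_forward(net, net_im2col(net, X[va, , drop = FALSE]),
                       length(va))$pooled
  } else {
    Pva <- net_im2col(net, X[va, , drop = FALSE])
  }

  # Adam state
  params <- list(fc_w = net$fc_w, fc_b = net$fc_b)
  if (!frozen) { params$W <- net$W; params$conv_bias <- net$conv_bias }
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  t_step <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  adam_step <- function(name, grad) {
    t <- t_step
    mstate[[name]] <<- beta1 * mstate[[name]] + (1 - beta1) * grad
    vstate[[name]] <<- beta2 * vstate[[name]] + (1 - beta2) * grad^2
    mh <- mstate[[name]] / (1 - beta1^t)
    vh <- vstate[[name]] / (1 - beta2^t)
    params[[name]] <<- params[[name]] - lr * mh / (sqrt(vh) + eps)
  }
  sync <- function() {
    net$fc_w <- params$fc_w; net$fc_b <- params$fc_b
    if (!frozen) { net$W <- params$W; net$conv_bias <- params$conv_bias }
    net
  }

  hist <- vector("list", max_epochs)
  best <- list(val = -Inf, epoch = 0L, net = sync())
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(n_tr)
      mse_acc <- 0
      for (b0 in seq(1L, n_tr, by = batch)) {
        bi <- perm[b0:min(b0 + batch - 1L, n_tr)]
        nb <- length(bi)
        if (frozen) {
          pooled_b <- Ftr[bi, , drop = FALSE]
          fw <- list(pooled = pooled_b,
                     pred = as.numeric(pooled_b %*% params$fc_w) + params$fc_b)
        } else {
          Pb <- as.matrix(Xtr[bi, , drop = FALSE] %*% op$St)
          dim(Pb) <- c(nb * n_conv, op$k2)
          nn <- sync()
          fw <- net_forward(nn, Pb, nb, want_argmax = TRUE)
        }
        err <- fw$pred - ytr[bi]
        mse_acc <- mse_acc + sum(err^2)
        dpred <- 2 * err / nb
        t_step <- t_step + 1
        adam_step("fc_w", crossprod(fw$pooled, dpred))
        adam_step("fc_b", sum(dpred))
        if (!frozen) {
          # route gradients through the pooled argmax positions
          C <- cfg$n_kernels
          np <- cfg$pooled_side^2
          dV <- matrix(0, nb * n_conv, C)
          gmat <- dpred * matrix(params$fc_w[, 1], nb, np * C, byrow = TRUE)
          on <- fw$pooled > 0       # ReLU gate: pooled max 0 -> no gradient
          for (k in seq_len(ncol(fw$win_pos))) {
            selk <- on & (fw$karg == k)
            if (!any(selk)) next
            idx <- which(selk, arr.ind = TRUE)
            q <- (idx[, 2] - 1L) %% np + 1L
            ch <- (idx[, 2] - 1L) %/% np + 1L
            pos <- fw$win_pos[cbind(q, rep.int(k, nrow(idx)))]
            rows <- (pos - 1L) * nb + idx[, 1]
            dV[cbind(rows, ch)] <- dV[cbind(rows, ch)] + gmat[selk]
          }
          adam_step("W", crossprod(Pb, dV))
          adam_step("conv_bias", colSums(dV))
        }
      }
      nn <- sync()
      val_pred <- if (frozen) {
        as.numeric(Fva %*% params$fc_w) + params$fc_b
      } else {
        net_forward(nn, Pva, length(va))$pred
      }
      val_r <- pearson(val_pred, yva, warn = FALSE)
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_mse = mse_acc / n_tr,
                                      val_pearson = val_r)
      if (val_r > best$val + 1e-9) {
        best <- list(val = val_r, epoch = epoch, net = nn)
      } else if (epoch - best$epoch >= patience) {
        break
      }
    }
  })
  out <- best$net
  out$history <- dplyr::bind_rows(hist)
  out$epochs_to_stop <- best$epoch
  out
}

#' Predict neuronal responses from a trained network
#'
#' @param object An `rf_net`.
#' @param stimuli A `stimulus_set` with matching side.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.rf_net <- function(object, stimuli, ...) {
  if (stimulus_side(stimuli) != object$config$input_side) {
    stop_invalid("stimulus side does not match the network input side")
  }
  X <- stimulus_matrix(stimuli)
  Pm2 <- net_im2col(object, X)
  net_forward(object, Pm2, nrow(X))$pred
}

#' Per-kernel importance scores of a fixed-front-end network
#'
#' For each frozen channel `j`, all other channels' readout weights are
#' zeroed (the readout bias is kept), the silenced network predicts the
#' test stimuli, and the Pearson correlation with the test responses is the
#' channel's importance. Undefined correlations (constant predictions)
#' score 0.
#'
#' @param net A trained fixed-variant `rf_net`.
#' @param stimuli Test `stimulus_set`.
#' @param y Test responses.
#' @return A tibble with `kernel` (bank index), `source_id`, and
#'   `importance`.
#' @export
kernel_importance <- function(net, stimuli, y) {
  if (!net$first_layer_frozen) {
    stop(errorCondition("importance scores require a fixed-front-end network",
                        class = c("rfpursuit_unsupported_variant", "error")))
  }
  cfg <- net$config
  X <- stimulus_matrix(stimuli)
  Pm2 <- net_im2col(net, X)
  fw <- net_forward(net, Pm2, nrow(X))
  np <- cfg$pooled_side^2
  C <- cfg$n_kernels
  scores <- vapply(seq_len(C), function(j) {
    w <- net$fc_w * 0
    cols <- (j - 1L) * np + seq_len(np)
    w[cols, 1] <- net$fc_w[cols, 1]
    pred <- as.numeric(fw$pooled %*% w) + net$fc_b
    pearson(pred, y, warn = FALSE)
  }, 0)
  tibble::tibble(kernel = seq_len(C),
                 source_id = cfg$front_end$info$source_id,
                 importance = scores)
}

#' @export
print.rf_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<rf_net %s>: %d channel(s) %dx%d, pool %d/%d -> %dx%d, %s\n",
              cfg$variant, cfg$n_kernels, cfg$kernel_size, cfg$kernel_size,
              cfg$pool_window, cfg$pool_stride, cfg$pooled_side,
              cfg$pooled_side,
              if (is.null(x$history)) "untrained" else
                sprintf("trained (stopped at epoch %d)", x$epochs_to_stop)))
  invisible(x)
}

#' @describeIn train_network Per-epoch training history as a tibble.
#' @param x,object An `rf_net`.
#' @param ... Unused.
#' @method tidy rf_net
#' @export
tidy.rf_net <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_mse = numeric(),
                          val_pearson = numeric()))
  }
  x$history
}

#' @describeIn train_network One-row summary (variant, parameter counts,
#'   stopping epoch, best validation Pearson).
#' @method glance rf_net
#' @export
glance.rf_net <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    n_kernels = x$config$n_kernels,
    frozen_front_end = x$first_layer_frozen,
    learnable_params = count_learnable_params(x),
    epochs_to_stop = x$epochs_to_stop,
    best_val_pearson = if (is.null(x$history)) NA_real_ else max(x$history$val_pearson)
  )
}
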