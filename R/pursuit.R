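# Pursuit regression estimators. Each stage fits one kernel and a quadratic
# link g(z) = a z^2 + b z + c to the current residual, where z is either the
# plain image/kernel dot product (ppr) or the maximum absolute valid
# cross-correlation response over image positions (cppr, cmpr). Stages are
# accepted while their pursuit contribution I -- the fraction of residual
# variance they explain -- stays above a floor, then reordered and pruned.

#' Pooled feature of a kernel on an image
#'
#' For `mode = "ppr"` the feature is the plain dot product between the
#' image and a same-sized kernel. For the convolutional modes the kernel
#' slides over the image ("valid": output `(w-d+1) x (w-d+1)`), responses
#' pass through an absolute-value layer, and a global max pool returns one
#' scalar: the strongest response of the kernel at any position, in either
#' contrast polarity.
#'
#' @param kernel A numeric matrix (side `d`; for ppr, `d` must equal the
#'   image side).
#' @param image A numeric matrix.
#' @param mode `"ppr"`, `"cppr"`, or `"cmpr"`.
#' @return A single numeric feature.
#' @examples
#' img <- matrix(rnorm(400), 20, 20)
#' pooled_feature(matrix(1, 9, 9) / 9, img, "cppr")
#' @export
pooled_feature <- function(kernel, image, mode = c("cppr", "ppr", "cmpr")) {
  mode <- match.arg(mode)
  if (mode == "ppr") {
    if (!all(dim(kernel) == dim(image))) {
      stop_invalid("ppr requires kernel and image of equal size")
    }
    return(sum(kernel * image))
  }
  d <- nrow(kernel)
  w <- nrow(image)
  h <- ncol(image)
  if (d > w || d > h) stop_invalid("kernel larger than image")
  best <- -Inf
  for (c in seq_len(h - d + 1L)) {
    for (r in seq_len(w - d + 1L)) {
      v <- abs(sum(image[r:(r + d - 1L), c:(c + d - 1L)] * kernel))
      if (v > best) best <- v
    }
  }
  best
}

#' Least-squares quadratic link fit
#'
#' Fits `g(z) = a z^2 + b z + c` to residuals by ordinary least squares on
#' the design `[z^2, z, 1]` (normal-equations optimum).
#'
#' @param features Numeric feature vector `z` (length >= 3, not all equal).
#' @param residuals Numeric residual vector of equal length.
#' @return A `quadratic_link`: list with `a`, `b`, `c`.
#' @examples
#' fit_quadratic_link(c(-1, 0, 1), c(1, 0, 1))  # a=1, b=0, c=0
#' @export
fit_quadratic_link <- function(features, residuals) {
  if (length(features) != length(residuals)) stop_invalid("length mismatch")
  if (length(features) < 3) stop_invalid("need at least 3 samples")
  if (max(features) - min(features) == 0) {
    stop(errorCondition("all features are identical: quadratic link is rank-deficient",
                        class = c("rfpursuit_rank_deficient", "error")))
  }
  X <- cbind(features^2, features, 1)
  fit <- stats::lm.fit(X, residuals)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  structure(list(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3])),
            class = "quadratic_link")
}

#' Evaluate a quadratic link
#' @param link A `quadratic_link`.
#' @param z Numeric vector.
#' @return `a z^2 + b z + c`.
#' @export
link_eval <- function(link, z) link$a * z^2 + link$b * z + link$c

#' Pursuit contribution of a fitted stage
#'
#' `I = 1 - sum((r - g(z))^2) / sum(r^2)`: the fraction of residual energy
#' explained by the stage. Equals 1 iff the fit is exact and 0 for the null
#' link `g = 0`.
#'
#' @param link A `quadratic_link`.
#' @param features Feature vector `z`.
#' @param residuals Residual vector `r` with `sum(r^2) > 0`.
#' @return The contribution `I` (<= 1).
#' @export
pursuit_contribution <- function(link, features, residuals) {
  se <- sum(residuals^2)
  if (se == 0) {
    stop(errorCondition("zero residual energy: contribution undefined",
                        class = c("rfpursuit_undefined_contribution", "error")))
  }
  1 - sum((residuals - link_eval(link, features))^2) / se
}

# Batched pooled features for a kernel matrix K (d^2 x C) over a cached
# im2col matrix Pm2 ((n * n_pos) x d^2). Returns list(z = n x C max-abs
# features, pos = n x C argmax position, sgn = n x C response sign).
pooled_features_cached <- function(Pm2, n, n_pos, K, want_arg = FALSE) {
  V <- Pm2 %*% K                              # (n*n_pos) x C
  C <- ncol(K)
  z <- matrix(0, n, C)
  pos <- if (want_arg) matrix(0L, n, C) else NULL
  sgn <- if (want_arg) matrix(0, n, C) else NULL
  for (j in seq_len(C)) {
    Vi <- matrix(V[, j], n, n_pos)
    A <- abs(Vi)
    p <- max.col(A, ties.method = "first")
    z[, j] <- A[cbind(seq_len(n), p)]
    if (want_arg) {
      pos[, j] <- p
      sgn[, j] <- sign(Vi[cbind(seq_len(n), p)])
    }
  }
  list(z = z, pos = pos, sgn = sgn)
}

# Closed-form link fit + contribution for every feature column; ties in the
# argmax break toward the lowest index.
best_dictionary_stage <- function(Z, r) {
  se <- sum(r^2)
  n <- nrow(Z)
  best <- list(I = -Inf, j = NA_integer_, link = NULL)
  for (j in seq_len(ncol(Z))) {
    z <- Z[, j]
    if (max(z) - min(z) == 0) next
    X <- cbind(z^2, z, 1)
    XtX <- crossprod(X)
    Xtr <- crossprod(X, r)
    cf <- tryCatch(solve(XtX, Xtr), error = function(e) NULL)
    if (is.null(cf)) {
      cf <- stats::lm.fit(X, r)$coefficients
      cf[is.na(cf)] <- 0
      cf <- matrix(cf)
    }
    I_j <- 1 - (se - sum(cf * Xtr)) / se
    if (I_j > best$I + 1e-12) {
      best <- list(I = I_j, j = j,
                   link = structure(list(a = cf[1], b = cf[2], c = cf[3]),
                                    class = "quadratic_link"))
    }
  }
  best
}

#' Fit a pursuit regression model
#'
#' Fits up to `M` stages to the responses. Modes:
#' \describe{
#'   \item{ppr}{image-sized kernels, dot-product features; each stage's
#'     kernel maximizes the contribution `I` by quasi-Newton ascent with
#'     random restarts (the link refit in closed form at every step).}
#'   \item{cppr}{small `kernel_side`-sized kernels with the
#'     abs-then-max-pool convolutional feature, optimized the same way
#'     (max-pool gradients flow through the argmax position).}
#'   \item{cmpr}{kernels chosen from `dictionary` by exhaustive search:
#'     every dictionary kernel's pooled features are cached once, each
#'     stage's link is fit in closed form for every kernel, and the
#'     contribution argmax wins (ties to the lowest index).}
#' }
#' After each accepted stage the residual is updated,
#' `r <- r - g(z)`; pursuit stops early when a stage's contribution falls
#' below `min_contribution`. Finally [reduce_redundant()] reorders stages by
#' contribution and prunes near-duplicates.
#'
#' @param stimuli A `stimulus_set`.
#' @param y Numeric response vector (nonzero variance).
#' @param M Maximum number of stages (default 10).
#' @param mode `"ppr"`, `"cppr"`, or `"cmpr"`.
#' @param kernel_side Kernel side `d` for the convolutional modes (default
#'   9). Ignored for ppr (forced to the image side).
#' @param dictionary A `kernel_bank` (required for cmpr).
#' @param min_contribution Stop when a stage explains less than this
#'   fraction of residual variance (default 0.01).
#' @param restarts Random restarts for the kernel optimization (default 3).
#' @param maxit `optim` iterations per restart (default 100).
#' @param reduce Run the redundancy-reduction pass (default `TRUE`).
#' @param epsilon Contribution tolerance used by [reduce_redundant()].
#' @param seed Integer seed (restart initializations and restart-selection
#'   split).
#' @param cache A [pursuit_feature_cache()] built on the same stimuli (and
#'   dictionary, for cmpr). When many neurons share one stimulus ensemble
#'   -- the usual study design -- passing the cache avoids recomputing the
#'   pooled dictionary features per neuron.
#' @return A `pursuit_model`.
#' @export
fit_pursuit <- function(stimuli, y, M = 10, mode = c("cppr", "ppr", "cmpr"),
                        kernel_side = 9, dictionary = NULL,
                        min_contribution = 0.01, restarts = 3, maxit = 100,
                        reduce = TRUE, epsilon = 0.005, seed = 1,
                        cache = NULL) {
  mode <- match.arg(mode)
  w <- stimulus_side(stimuli)
  n <- length(stimuli)
  if (length(y) != n) stop_invalid("y must have one response per stimulus")
  if (stats::sd(y) == 0) stop_invalid("y has zero variance")
  if (mode == "cmpr") {
    if (is.null(dictionary) || length(dictionary) == 0) {
      stop_invalid("cmpr requires a non-empty dictionary")
    }
    kernel_side <- kernel_side(dictionary)
  }
  if (mode == "ppr") kernel_side <- w
  X <- stimulus_matrix(stimuli)

  if (is.null(cache)) {
    cache <- pursuit_cache(X, w, kernel_side, mode, dictionary)
  } else {
    if (!identical(cache$mode, mode) || !identical(cache$n, n)) {
      stop_invalid("cache does not match this mode/stimulus set")
    }
  }
  r <- y
  stages <- list()
  m <- 0L
  while (m < M) {
    if (sum(r^2) == 0) break
    stage <- switch(mode,
      cmpr = {
        best <- best_dictionary_stage(cache$Zd, r)
        if (!is.finite(best$I)) NULL else {
          list(kernel = dictionary$kernels[, , best$j],
               link = best$link, contribution = best$I,
               dict_index = best$j, z = cache$Zd[, best$j])
        }
      },
      fit_pursuit_stage(cache, r, restarts, maxit,
                        seed = seed + 97L * m, mode = mode)
    )
    if (is.null(stage) || stage$contribution < min_contribution) break
    r <- r - link_eval(stage$link, stage$z)
    stages[[length(stages) + 1L]] <- stage
    m <- m + 1L
  }
  model <- structure(
    list(mode = mode, stages = stages, image_side = w,
         kernel_side = kernel_side,
         dictionary_name = if (is.null(dictionary)) NULL else dictionary$name),
    class = "pursuit_model"
  )
  if (reduce && length(stages) > 1) {
    model <- reduce_redundant(model, stimuli, y, epsilon = epsilon)
  }
  model
}

#' Precompute pursuit features for a stimulus ensemble
#'
#' Builds the im2col patch matrix (conv modes) and, for cmpr, the pooled
#' feature of every dictionary kernel on every stimulus. One model is
#' typically fit per neuron on a shared stimulus ensemble; reusing the
#' cache across [fit_pursuit()] calls makes the per-neuron cost just the
#' closed-form link fits.
#'
#' @param stimuli A `stimulus_set`.
#' @param mode Pursuit mode the cache is for.
#' @param kernel_side Kernel side `d` (conv modes).
#' @param dictionary `kernel_bank` (required for cmpr).
#' @return An opaque cache object for `fit_pursuit(..., cache = )`.
#' @export
pursuit_feature_cache <- function(stimuli, mode = c("cppr", "ppr", "cmpr"),
                                  kernel_side = 9, dictionary = NULL) {
  mode <- match.arg(mode)
  w <- stimulus_side(stimuli)
  if (mode == "cmpr") {
    if (is.null(dictionary) || length(dictionary) == 0) {
      stop_invalid("cmpr requires a non-empty dictionary")
    }
    kernel_side <- kernel_side(dictionary)
  }
  if (mode == "ppr") kernel_side <- w
  pursuit_cache(stimulus_matrix(stimuli), w, kernel_side, mode, dictionary)
}

# Shared per-fit caches: the im2col matrix for conv modes and the cached
# dictionary features for cmpr.
pursuit_cache <- function(X, w, d, mode, dictionary) {
  n <- nrow(X)
  if (mode == "ppr") {
    return(list(mode = "ppr", X = X, n = n))
  }
  op <- make_conv_op(w, w, d)
  Pm2 <- as.matrix(X %*% op$St)
  dim(Pm2) <- c(n * op$n_pos, op$k2)
  out <- list(mode = mode, n = n, n_pos = op$n_pos, Pm2 = Pm2, d = d)
  if (mode == "cmpr") {
    D <- bank_matrix(dictionary)
    nd <- ncol(D)
    Zd <- matrix(0, n, nd)
    for (start in seq(1L, nd, by = 64L)) {
      jj <- start:min(start + 63L, nd)
      Zd[, jj] <- pooled_features_cached(Pm2, n, op$n_pos, D[, jj, drop = FALSE])$z
    }
    out$Zd <- Zd
  }
  out
}

# Gradient-based stage optimization for ppr / cppr: maximize I(F) with the
# link refit in closed form (envelope gradient); restarts selected on a
# held-out fifth of the samples, then the link is refit on all samples.
fit_pursuit_stage <- function(cache, r, restarts, maxit, seed, mode) {
  n <- cache$n
  n_par <- if (cache$mode == "ppr") ncol(cache$X) else cache$d^2
  hold <- with_seed(seed, sample.int(n, max(3L, floor(n / 5))))
  fit_idx <- setdiff(seq_len(n), hold)

  feat <- function(F_vec) {
    if (cache$mode == "ppr") {
      list(z = as.numeric(cache$X %*% F_vec))
    } else {
      V <- matrix(cache$Pm2 %*% F_vec, n, cache$n_pos)
      A <- abs(V)
      p <- max.col(A, ties.method = "first")
      list(z = A[cbind(seq_len(n), p)], pos = p,
           sgn = sign(V[cbind(seq_len(n), p)]))
    }
  }
  neg_I <- function(F_vec) {
    ft <- feat(F_vec)
    z <- ft$z[fit_idx]
    if (max(z) - min(z) == 0) return(0)
    link <- fit_quadratic_link(z, r[fit_idx])
    -pursuit_contribution(link, z, r[fit_idx])
  }
  neg_I_grad <- function(F_vec) {
    ft <- feat(F_vec)
    z_all <- ft$z
    z <- z_all[fit_idx]
    if (max(z) - min(z) == 0) return(numeric(n_par))
    link <- fit_quadratic_link(z, r[fit_idx])
    wres <- numeric(n)
    wres[fit_idx] <- (r[fit_idx] - link_eval(link, z)) *
      (2 * link$a * z + link$b) * (2 / sum(r[fit_idx]^2))
    if (cache$mode == "ppr") {
      -as.numeric(crossprod(cache$X[fit_idx, , drop = FALSE], wres[fit_idx]))
    } else {
      rows <- (ft$pos - 1L) * n + seq_len(n)
      wsgn <- wres * ft$sgn
      -as.numeric(crossprod(cache$Pm2[rows, , drop = FALSE], wsgn))
    }
  }
  best <- NULL
  for (rs in seq_len(restarts)) {
    F0 <- with_seed(seed + rs, stats::rnorm(n_par))
    F0 <- F0 / l2norm(F0)
    opt <- tryCatch(
      stats::optim(F0, neg_I, neg_I_grad, method = "BFGS",
                   control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    ft <- feat(opt$par)
    zh <- ft$z[hold]
    val_I <- if (max(zh) - min(zh) == 0 || sum(r[hold]^2) == 0) {
      -Inf
    } else {
      link_h <- fit_quadratic_link(ft$z[fit_idx], r[fit_idx])
      tryCatch(pursuit_contribution(link_h, zh, r[hold]), error = function(e) -Inf)
    }
    if (is.null(best) || val_I > best$val_I) best <- list(par = opt$par, val_I = val_I)
  }
  if (is.null(best)) return(NULL)
  F_hat <- best$par / l2norm(best$par)
  ft <- feat(F_hat)
  if (max(ft$z) - min(ft$z) == 0) return(NULL)
  link <- fit_quadratic_link(ft$z, r)
  I_full <- pursuit_contribution(link, ft$z, r)
  kern <- matrix(F_hat, sqrt(n_par), sqrt(n_par))
  list(kernel = kern, link = link, contribution = I_full,
       dict_index = NA_integer_, z = ft$z)
}

#' Reorder stages and prune redundant ones
#'
#' Stages are reordered by descending contribution, then scanned from the
#' least important up: a stage is dropped when its kernel has absolute
#' cosine similarity above 0.95 with a retained kernel, or when removing it
#' (and refitting the remaining links sequentially on the training data)
#' costs less than `epsilon` of variance explained. The top stage is never
#' dropped.
#'
#' @param model A fitted `pursuit_model`.
#' @param stimuli The training `stimulus_set`.
#' @param y The training responses.
#' @param epsilon Tolerated variance-explained loss per dropped stage.
#' @return The pruned `pursuit_model`.
#' @export
reduce_redundant <- function(model, stimuli, y, epsilon = 0.005) {
  ns <- length(model$stages)
  if (ns <= 1) return(model)
  ord <- order(vapply(model$stages, `[[`, 0, "contribution"), decreasing = TRUE)
  stages <- model$stages[ord]
  Z <- vapply(stages, `[[`, numeric(length(y)), "z")
  ve <- function(keep) {
    refit <- refit_links(Z[, keep, drop = FALSE], y)
    refit$ve
  }
  keep <- seq_along(stages)
  ve_full <- ve(keep)
  for (i in rev(seq_along(stages))[-length(stages)]) {  # never drop the top stage
    if (!(i %in% keep)) next
    others <- setdiff(keep, i)
    ki <- as.numeric(stages[[i]]$kernel)
    sims <- vapply(others, function(j) {
      kj <- as.numeric(stages[[j]]$kernel)
      if (length(kj) != length(ki)) return(0)
      abs(sum(ki * kj)) / (l2norm(ki) * l2norm(kj))
    }, 0)
    if (any(sims > 0.95) || ve_full - ve(others) < epsilon) {
      keep <- others
      ve_full <- ve(keep)
    }
  }
  refit <- refit_links(Z[, keep, drop = FALSE], y)
  model$stages <- lapply(seq_along(keep), function(s) {
    st <- stages[[keep[s]]]
    st$link <- refit$links[[s]]
    st$contribution <- refit$contributions[s]
    st
  })
  model
}

# Sequential refit of the quadratic links for a fixed ordered set of stage
# features; returns links, per-stage contributions, and total variance
# explained (R^2 against the centered responses).
refit_links <- function(Z, y) {
  r <- y
  links <- vector("list", ncol(Z))
  contribs <- numeric(ncol(Z))
  for (s in seq_len(ncol(Z))) {
    z <- Z[, s]
    if (max(z) - min(z) == 0 || sum(r^2) == 0) {
      links[[s]] <- structure(list(a = 0, b = 0, c = 0), class = "quadratic_link")
      contribs[s] <- 0
      next
    }
    links[[s]] <- fit_quadratic_link(z, r)
    contribs[s] <- pursuit_contribution(links[[s]], z, r)
    r <- r - link_eval(links[[s]], z)
  }
  denom <- sum((y - mean(y))^2)
  list(links = links, contributions = contribs,
       ve = if (denom == 0) 0 else 1 - sum(r^2) / denom)
}

#' Predict from a pursuit model
#'
#' Per stimulus, the prediction is the sum over stages of the quadratic
#' link applied to the stage kernel's pooled feature. An empty model
#' predicts 0 everywhere.
#'
#' @param object A `pursuit_model`.
#' @param stimuli A `stimulus_set` whose side matches the model.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.pursuit_model <- function(object, stimuli, ...) {
  w <- stimulus_side(stimuli)
  if (w != object$image_side) {
    stop_invalid("stimulus side ", w, " does not match model side ",
                 object$image_side)
  }
  n <- length(stimuli)
  if (length(object$stages) == 0) return(numeric(n))
  X <- stimulus_matrix(stimuli)
  if (object$mode == "ppr") {
    preds <- numeric(n)
    for (st in object$stages) {
      z <- as.numeric(X %*% as.numeric(st$kernel))
      preds <- preds + link_eval(st$link, z)
    }
    return(preds)
  }
  op <- make_conv_op(w, w, object$kernel_side)
  Pm2 <- as.matrix(X %*% op$St)
  dim(Pm2) <- c(n * op$n_pos, op$k2)
  K <- vapply(object$stages, function(st) as.numeric(st$kernel),
              numeric(object$kernel_side^2))
  Z <- pooled_features_cached(Pm2, n, op$n_pos, K)$z
  preds <- numeric(n)
  for (s in seq_along(object$stages)) {
    preds <- preds + link_eval(object$stages[[s]]$link, Z[, s])
  }
  preds
}

#' @export
print.pursuit_model <- function(x, ...) {
  cat(sprintf("<pursuit_model %s>: %d stage(s), kernel %dx%d on %dx%d stimuli\n",
              x$mode, length(x$stages), x$kernel_side, x$kernel_side,
              x$image_side, x$image_side))
  if (length(x$stages)) {
    cat("  contributions:",
        paste(sprintf("%.3f", vapply(x$stages, `[[`, 0, "contribution")),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn fit_pursuit Per-stage summary: one row per stage with the
#'   link coefficients, contribution, and dictionary index (cmpr).
#' @param x,object A `pursuit_model`.
#' @param ... Unused.
#' @method tidy pursuit_model
#' @export
tidy.pursuit_model <- function(x, ...) {
  if (length(x$stages) == 0) {
    return(tibble::tibble(stage = integer(), contribution = numeric(),
                          a = numeric(), b = numeric(), c = numeric(),
                          dict_index = integer()))
  }
  tibble::tibble(
    stage = seq_along(x$stages),
    contribution = vapply(x$stages, `[[`, 0, "contribution"),
    a = vapply(x$stages, function(s) s$link$a, 0),
    b = vapply(x$stages, function(s) s$link$b, 0),
    c = vapply(x$stages, function(s) s$link$c, 0),
    dict_index = vapply(x$stages, function(s) {
      if (is.null(s$dict_index)) NA_integer_ else as.integer(s$dict_index)
    }, 0L)
  )
}

#' @describeIn fit_pursuit One-row model summary.
#' @method glance pursuit_model
#' @export
glance.pursuit_model <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_stages = length(x$stages),
    kernel_side = x$kernel_side,
    image_side = x$image_side,
    n_parameters = length(x$stages) * (x$kernel_side^2 + 3)
  )
}
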