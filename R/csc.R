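# Convolutional sparse coding: learn a dictionary of small kernels whose
# spatial convolutions with sparse coefficient maps reconstruct image
# patches. Training alternates FISTA sparse coding with a projected-gradient
# dictionary update. A synthetic image generator (dead-leaves, pink noise)
# stands in for natural scenes.

#' Generate synthetic training images
#'
#' Grayscale images in \[0, 1\] emulating natural-scene statistics:
#' `dead_leaves` draws occluding random disks and rectangles with random
#' intensities (sharp occlusion edges, broad object-size distribution);
#' `pink_noise` filters white noise to a 1/f amplitude spectrum.
#' Deterministic given `seed`.
#'
#' @param n Number of images (>= 1).
#' @param size Image side in px (>= 32).
#' @param kind `"dead_leaves"` or `"pink_noise"`.
#' @param seed Integer seed.
#' @return A `size x size x n` array.
#' @examples
#' imgs <- generate_training_images(4, 64, "dead_leaves", seed = 1)
#' range(imgs)
#' @export
generate_training_images <- function(n, size = 128,
                                     kind = c("dead_leaves", "pink_noise"),
                                     seed = 1) {
  kind <- match.arg(kind)
  if (n < 1) stop_invalid("n must be >= 1")
  if (size < 32) stop_invalid("size must be >= 32")
  with_seed(seed, {
    out <- array(0, dim = c(size, size, n))
    for (i in seq_len(n)) {
      out[, , i] <- if (kind == "dead_leaves") {
        dead_leaves_image(size)
      } else {
        pink_noise_image(size)
      }
    }
    out
  })
}

# One dead-leaves image: back-to-front occluding shapes until covered.
dead_leaves_image <- function(size, n_shapes = 120) {
  img <- matrix(stats::runif(1), size, size)
  xg <- matrix(rep(seq_len(size), each = size), size, size)
  yg <- matrix(rep(seq_len(size), times = size), size, size)
  for (s in seq_len(n_shapes)) {
    cx <- stats::runif(1, 1, size)
    cy <- stats::runif(1, 1, size)
    val <- stats::runif(1)
    # power-law-ish radius distribution for scale diversity
    r <- size * 0.04 / stats::runif(1, 0.08, 1)
    mask <- if (stats::runif(1) < 0.5) {
      (xg - cx)^2 + (yg - cy)^2 <= r^2
    } else {
      th <- stats::runif(1, 0, pi)
      u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      abs(u) <= r & abs(v) <= r * stats::runif(1, 0.3, 1)
    }
    img[mask] <- val
  }
  img
}

#' Whiten an image stack
#'
#' Applies the classical sparse-coding whitening filter
#' `R(f) = f * exp(-(f / f0)^4)` in the frequency domain: it flattens the
#' 1/f amplitude spectrum of natural-looking imagery while cutting
#' frequencies near Nyquist. Whitened inputs make dictionary learning
#' recover bandpass (edge/arc-like) atoms instead of low-pass blobs.
#'
#' @param images A `h x w x n` array.
#' @param f0 Cutoff frequency in cycles/px (default 0.35).
#' @return A whitened array of the same shape (zero-mean images).
#' @export
whiten_images <- function(images, f0 = 0.35) {
  d <- dim(images)
  if (length(d) != 3L) stop_invalid("images must be a h x w x n array")
  if (d[1] != d[2]) stop_invalid("whitening expects square images")
  f <- fft_radial_freq(d[1])
  filt <- f * exp(-(f / f0)^4)
  out <- images
  for (i in seq_len(d[3])) {
    W <- stats::fft(images[, , i]) * filt
    out[, , i] <- Re(stats::fft(W, inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

# One pink-noise image: white noise shaped to 1/f amplitude, rescaled to [0,1].
pink_noise_image <- function(size) {
  wn <- matrix(stats::rnorm(size^2), size, size)
  W <- stats::fft(wn)
  f <- fft_radial_freq(size)
  amp <- 1 / pmax(f, 1 / size)
  shaped <- Re(stats::fft(W * amp, inverse = TRUE)) / size^2
  rng <- range(shaped)
  (shaped - rng[1]) / (rng[2] - rng[1])
}

#' Sample zero-mean patches from an image stack
#'
#' Draws `n` square patches at uniform random positions across the stack and
#' removes each patch's mean (the coding model reconstructs local structure,
#' not mean luminance). Deterministic given `seed`.
#'
#' @param images A `h x w x m` array.
#' @param patch Patch side in px (default 25), at most the image side.
#' @param n Number of patches.
#' @param seed Integer seed.
#' @return A `patch_set`: list with `patches` (`patch x patch x n` array)
#'   and `p` (patch side).
#' @export
sample_patches <- function(images, patch = 25, n = 1000, seed = 1) {
  d <- dim(images)
  if (patch > d[1] || patch > d[2]) {
    stop_invalid("patch side ", patch, " exceeds image size ", d[1], "x", d[2])
  }
  with_seed(seed, {
    out <- array(0, dim = c(patch, patch, n))
    img_idx <- sample.int(d[3], n, replace = TRUE)
    r0 <- sample.int(d[1] - patch + 1L, n, replace = TRUE)
    c0 <- sample.int(d[2] - patch + 1L, n, replace = TRUE)
    for (i in seq_len(n)) {
      p <- images[r0[i]:(r0[i] + patch - 1L), c0[i]:(c0[i] + patch - 1L), img_idx[i]]
      out[, , i] <- p - mean(p)
    }
    structure(list(patches = out, p = patch), class = "patch_set")
  })
}

#' Sparse convolutional encoding of images
#'
#' Finds coefficient maps `z_c` minimizing
#' `0.5 * ||x - sum_c kernel_c * z_c||^2 + lambda * sum |z|`
#' by FISTA-accelerated iterative soft-thresholding with step `1/L`, `L`
#' estimated by power iteration on the dictionary operator. Coefficient maps
#' are image-sized ("same" geometry with zero padding): the reconstruction
#' is the center crop of the full convolution, and its exact adjoint is
#' zero-padded valid correlation, so boundary structure can be encoded. The
#' objective is non-increasing over iterations (monitored; a FISTA restart
#' falls back to the previous iterate on any increase).
#'
#' @param images A single `p x p` matrix or `p x p x n` array to encode.
#' @param bank A unit-normalized `kernel_bank` (the dictionary).
#' @param lambda Sparsity weight (> 0 for sparse solutions; 0 allowed).
#' @param steps Number of FISTA iterations (>= 1).
#' @return A list with `coeff` (`(n * p^2) x C` coefficient matrix, rows
#'   image-fastest then map position), `objective` (per-iteration trace),
#'   `recon` (`n x p^2` reconstruction matrix) and the operator geometry
#'   `op`.
#' @export
sparse_encode <- function(images, bank, lambda, steps = 50) {
  if (!bank$normalized) {
    stop_invalid("sparse_encode() requires a unit-normalized bank")
  }
  if (steps < 1) stop_invalid("steps must be >= 1")
  if (length(dim(images)) == 2L) images <- array(images, dim = c(dim(images), 1L))
  p <- dim(images)[1]
  X <- stack_to_matrix(images)
  K <- bank_matrix(bank)
  op <- make_same_op(p, kernel_side(bank))
  L <- operator_norm_sq(op, K)
  fista(X, K, op, lambda, steps, L)
}

# "Same"-geometry conv operator: coefficient maps are p x p; the forward map
# A z = center-crop(conv_full(z, K)) and its exact adjoint
# A^T x = conv_corr_valid(zero-pad(x), K) share one padded valid-window
# operator over (p+k-1)-sided frames.
make_same_op <- function(p, k) {
  pad <- (k - 1L) / 2L
  P <- p + k - 1L
  base <- make_conv_op(P, P, k)             # n_pos = p^2
  rr <- rep(seq_len(p) + pad, times = p)
  cc <- rep(seq_len(p) + pad, each = p)
  center_cols <- (cc - 1L) * P + rr
  c(base, list(p = p, pad = pad, P = P, center_cols = center_cols))
}

same_pad <- function(op, X) {
  Xp <- matrix(0, nrow(X), op$P * op$P)
  Xp[, op$center_cols] <- X
  Xp
}

# A^T x for the same-geometry operator; X: n x p^2 -> (n*p^2) x C.
same_corr <- function(op, X, K) {
  conv_corr_valid(op, same_pad(op, X), K)
}

# A z: z ((n*p^2) x C) -> n x p^2 reconstruction.
same_recon <- function(op, z, K) {
  conv_adjoint(op, z, K)[, op$center_cols, drop = FALSE]
}

# Largest eigenvalue of A^T A by power iteration.
operator_norm_sq <- function(op, K, iters = 30, seed = 71) {
  v <- with_seed(seed, matrix(stats::rnorm(op$n_pos * ncol(K)), op$n_pos, ncol(K)))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(iters)) {
    img <- same_recon(op, v, K)             # 1 x p^2
    w <- same_corr(op, img, K)              # n_pos x C
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

fista <- function(X, K, op, lambda, steps, L) {
  n <- nrow(X)
  nz <- n * op$n_pos
  C <- ncol(K)
  z <- matrix(0, nz, C)
  y <- z
  t_acc <- 1
  obj <- numeric(steps)
  objective <- function(zz) {
    recon <- same_recon(op, zz, K)
    0.5 * sum((X - recon)^2) + lambda * sum(abs(zz))
  }
  prev_obj <- objective(z)
  for (it in seq_len(steps)) {
    recon <- same_recon(op, y, K)
    grad <- same_corr(op, recon - X, K)
    z_new <- soft_threshold(y - grad / L, lambda / L)
    o_new <- objective(z_new)
    if (o_new > prev_obj) {
      # restart: plain ISTA step from z keeps the trace non-increasing
      recon <- same_recon(op, z, K)
      grad <- same_corr(op, recon - X, K)
      z_new <- soft_threshold(z - grad / L, lambda / L)
      o_new <- objective(z_new)
      if (o_new > prev_obj) {
        z_new <- z
        o_new <- prev_obj
      }
      t_acc <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- z_new + ((t_acc - 1) / t_new) * (z_new - z)
    z <- z_new
    t_acc <- t_new
    prev_obj <- o_new
    obj[it] <- o_new
  }
  list(coeff = z, objective = obj, recon = same_recon(op, z, K), op = op)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Configuration for convolutional sparse coding
#'
#' @param n_channels Dictionary size (the study used 16-256; default 64).
#' @param kernel_size Odd kernel side (default 9).
#' @param sparsity_weight L1 penalty weight `lambda` (> 0).
#' @param n_alternations Coding/update alternations (default 10).
#' @param coder_steps FISTA iterations per coding pass (default 30).
#' @param seed Integer seed controlling initialization.
#' @return A `csc_config` list.
#' @export
csc_config <- function(n_channels = 64, kernel_size = 9, sparsity_weight = 0.1,
                       n_alternations = 10, coder_steps = 30, seed = 1) {
  if (n_channels < 1) stop_invalid("n_channels must be >= 1")
  kernel_size <- check_odd_size(kernel_size)
  if (sparsity_weight < 0) stop_invalid("sparsity_weight must be >= 0")
  structure(list(n_channels = n_channels, kernel_size = kernel_size,
                 sparsity_weight = sparsity_weight,
                 n_alternations = n_alternations,
                 coder_steps = coder_steps, seed = seed),
            class = "csc_config")
}

#' Learn a convolutional sparse coding dictionary
#'
#' Alternates sparse coding of the patches (FISTA, see [sparse_encode()])
#' with a dictionary update: one gradient step on the reconstruction error
#' with coefficients fixed, followed by per-kernel projection to the unit L2
#' sphere. Kernels never active in an alternation are re-seeded from a
#' random patch crop to avoid collapsed channels. The total objective over
#' the training set is non-increasing across alternations (up to the
#' re-seeding of dead kernels, which only touches inactive channels).
#'
#' @param patches A `patch_set` from [sample_patches()].
#' @param config A `csc_config`.
#' @return A unit-normalized `kernel_bank` of `n_channels` kernels with an
#'   `objective` attribute (per-alternation trace).
#' @export
learn_csc_dictionary <- function(patches, config) {
  p <- patches$p
  k <- config$kernel_size
  if (p <= k) stop_invalid("patch side must exceed kernel size")
  X <- stack_to_matrix(patches$patches)
  n <- nrow(X)
  C <- config$n_channels
  op <- make_same_op(p, k)
  # initialize atoms from data samples (random zero-mean patch crops), the
  # standard dictionary-learning warm start; falls back to Gaussian noise
  # for degenerate (constant) crops
  K <- with_seed(config$seed, {
    vapply(seq_len(C), function(j) {
      crop <- patches$patches[
        sample.int(p - k + 1L, 1) + 0:(k - 1L),
        sample.int(p - k + 1L, 1) + 0:(k - 1L),
        sample.int(n, 1)
      ]
      crop <- crop - mean(crop)
      if (sum(crop^2) < 1e-12) crop <- matrix(stats::rnorm(k * k), k, k)
      as.numeric(unit_norm(crop))
    }, numeric(k * k))
  })
  lambda <- config$sparsity_weight
  trace <- numeric(config$n_alternations)
  step0 <- 1
  for (alt in seq_len(config$n_alternations)) {
    L <- operator_norm_sq(op, K)
    enc <- fista(X, K, op, lambda, config$coder_steps, L)
    z <- enc$coeff
    obj_now <- utils::tail(enc$objective, 1)
    # dictionary gradient: d/dK 0.5||X - A(z) K||^2, coefficients fixed
    resid <- same_pad(op, enc$recon - X)
    gK <- dict_kernel_grad(op, resid, z)
    # backtracking line search on the coding objective with z fixed
    step <- step0
    repeat {
      K_try <- K - step * gK
      nrm <- sqrt(colSums(K_try^2))
      nrm[nrm == 0] <- 1
      K_try <- sweep(K_try, 2, nrm, "/")
      obj_try <- 0.5 * sum((X - same_recon(op, z, K_try))^2) + lambda * sum(abs(z))
      if (obj_try <= obj_now || step < 1e-8) break
      step <- step / 2
    }
    if (obj_try <= obj_now) {
      K <- K_try
      obj_now <- obj_try
      step0 <- step * 2
    }
    # re-seed dead kernels from random patch crops
    active <- colSums(abs(matrix(z, n * op$n_pos, C))) > 0
    if (any(!active) && sum(abs(X)) > 0) {
      K[, !active] <- with_seed(config$seed + alt, {
        vapply(which(!active), function(j) {
          i <- sample.int(n, 1)
          r0 <- sample.int(p - k + 1L, 1)
          c0 <- sample.int(p - k + 1L, 1)
          patch <- patches$patches[r0:(r0 + k - 1L), c0:(c0 + k - 1L), i]
          as.numeric(unit_norm(patch - mean(patch)))
        }, numeric(k * k))
      })
    }
    trace[alt] <- obj_now
  }
  bank <- kernel_bank(
    array(K, dim = c(k, k, C)),
    tibble::tibble(family = "csc", scale_index = 0L,
                   orientation_deg = NA_real_, rotation_index = 0L,
                   source_id = sprintf("csc%03d", seq_len(C))),
    name = sprintf("csc_%d", C), normalized = TRUE
  )
  attr(bank, "objective") <- trace
  bank
}

# Gradient of 0.5||X - recon||^2 w.r.t. the kernels for fixed coefficients:
# valid correlation of each coefficient map with the residual image, summed
# over images. Uses the same im2col operator transposed over roles.
dict_kernel_grad <- function(op, resid, z) {
  # resid: n x p^2 ; z: (n*n_pos) x C
  # dK[e, c] = sum_{i, pos} resid[i, pix(pos,e)] * z[(i,pos), c]
  G <- as.matrix(resid %*% op$St)            # n x (n_pos*k2), pos-fastest
  n <- nrow(resid)
  dim(G) <- c(n * op$n_pos, op$k2)
  t(G) %*% z                                 # k2 x C
}

#' Held-out reconstruction error of a dictionary
#'
#' Mean squared reconstruction error per patch after sparse encoding at
#' `lambda` (capacity diagnostic: larger dictionaries should do no worse).
#'
#' @param bank A `kernel_bank`.
#' @param patches A `patch_set`.
#' @param lambda Sparsity weight.
#' @param steps FISTA iterations.
#' @return Mean per-patch squared reconstruction error.
#' @export
csc_reconstruction_error <- function(bank, patches, lambda, steps = 30) {
  X <- stack_to_matrix(patches$patches)
  enc <- sparse_encode(patches$patches, bank, lambda, steps)
  mean(rowSums((X - enc$recon)^2))
}
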