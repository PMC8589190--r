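# Kernel banks: ordered, index-addressable sets of square 2-D kernels with
# per-kernel metadata. Banks are the front-ends of the fixed-kernel networks
# and the dictionaries searched by matching pursuit.

#' Construct a kernel bank
#'
#' A kernel bank is an ordered collection of square 2-D kernels sharing one
#' (odd) side length, together with per-kernel metadata. Selection results
#' elsewhere in the package are reported as indices into this order, so the
#' order is stable and part of the object's identity.
#'
#' @param kernels A `k x k x n` numeric array (or a list of `k x k`
#'   matrices) of kernels with odd side `k`.
#' @param info Optional tibble with one row per kernel and columns
#'   `family`, `scale_index`, `orientation_deg`, `rotation_index`,
#'   `source_id`. Missing columns are filled with defaults.
#' @param name Bank name (used in printing and serialization).
#' @param normalized If `TRUE`, every kernel is projected to unit L2 norm.
#' @return An object of class `kernel_bank`.
#' @examples
#' b <- gabor_bank(3, 8)
#' length(b)
#' tidy(b)
#' @export
kernel_bank <- function(kernels, info = NULL, name = "bank", normalized = TRUE) {
  if (is.list(kernels)) {
    k <- nrow(kernels[[1]])
    kernels <- array(unlist(kernels), dim = c(k, k, length(kernels)))
  }
  if (length(dim(kernels)) != 3L || dim(kernels)[1] != dim(kernels)[2]) {
    stop_invalid("kernels must be a k x k x n array of square kernels")
  }
  if (!all(is.finite(kernels))) stop_invalid("kernels must have finite entries")
  check_odd_size(dim(kernels)[1])
  n <- dim(kernels)[3]
  defaults <- tibble::tibble(
    family = rep("derived", n),
    scale_index = rep(NA_integer_, n),
    orientation_deg = rep(NA_real_, n),
    rotation_index = rep(0L, n),
    source_id = paste0("k", seq_len(n))
  )
  if (is.null(info)) {
    info <- defaults
  } else {
    info <- tibble::as_tibble(info)
    if (nrow(info) != n) stop_invalid("info must have one row per kernel")
    for (col in names(defaults)) {
      if (!col %in% names(info)) info[[col]] <- defaults[[col]]
    }
    info <- info[, names(defaults)]
  }
  if (normalized) {
    for (i in seq_len(n)) kernels[, , i] <- unit_norm(kernels[, , i])
  }
  structure(
    list(kernels = kernels, info = info, name = name, normalized = normalized),
    class = "kernel_bank"
  )
}

#' @export
length.kernel_bank <- function(x) dim(x$kernels)[3]

#' @export
print.kernel_bank <- function(x, ...) {
  cat(sprintf("<kernel_bank '%s'>: %d kernels of %dx%d px%s\n",
              x$name, length(x), kernel_side(x), kernel_side(x),
              if (x$normalized) ", unit L2 norm" else ""))
  fam <- table(x$info$family)
  cat("  families:", paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.kernel_bank` <- function(x, i) {
  i <- seq_len(length(x))[i]
  kernel_bank(x$kernels[, , i, drop = FALSE], x$info[i, ],
              name = x$name, normalized = x$normalized)
}

#' Kernel side length of a bank
#' @param bank A `kernel_bank`.
#' @return Integer side length.
#' @export
kernel_side <- function(bank) dim(bank$kernels)[1]

#' Bank kernels as a `k^2 x n` matrix (columns are vectorized kernels)
#' @param bank A `kernel_bank`.
#' @return Numeric matrix.
#' @export
bank_matrix <- function(bank) {
  d <- dim(bank$kernels)
  matrix(bank$kernels, d[1] * d[2], d[3])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-kernel metadata of a bank
#' @param x A `kernel_bank`.
#' @param ... Unused.
#' @return A tibble with one row per kernel (`index`, `family`,
#'   `scale_index`, `orientation_deg`, `rotation_index`, `source_id`,
#'   `l2_norm`, `high_freq_power`).
#' @method tidy kernel_bank
#' @export
tidy.kernel_bank <- function(x, ...) {
  n <- length(x)
  tibble::tibble(
    index = seq_len(n),
    x$info,
    l2_norm = vapply(seq_len(n), function(i) l2norm(x$kernels[, , i]), 0),
    high_freq_power = vapply(seq_len(n), function(i) {
      high_freq_power_fraction(x$kernels[, , i])
    }, 0)
  )
}

#' Gabor wavelet bank
#'
#' Builds `n_scales * n_orientations` even-phase Gabor kernels. The scale-`j`
#' wavelength is `3 * 2^j` px with Gaussian envelope `sigma = 0.56 * lambda`
#' and aspect ratio 1 (standard V1 wavelet conventions covering the default
#' 9 x 9 support). Orientations are evenly spaced on \[0, 180). Each kernel
#' is DC-removed (zero mean) and, by default, unit-L2 normalized. Oriented
#' kernels are produced by bilinear rotation of the 0-degree kernel so that
#' the whole family shares one resampling convention.
#'
#' @param n_scales Number of scales (>= 1).
#' @param n_orientations Number of orientations (>= 1).
#' @param size Odd kernel side length (default 9).
#' @param normalized Unit-normalize each kernel (default `TRUE`).
#' @return A `kernel_bank` of `n_scales * n_orientations` kernels, ordered
#'   scale-major then orientation.
#' @examples
#' gabor_bank(3, 8, 9)
#' @export
gabor_bank <- function(n_scales = 3, n_orientations = 8, size = 9, normalized = TRUE) {
  if (n_scales < 1 || n_orientations < 1) {
    stop_invalid("n_scales and n_orientations must be >= 1")
  }
  size <- check_odd_size(size)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - c0, each = size), size, size)
  y <- matrix(rep(seq_len(size) - c0, times = size), size, size)
  kernels <- vector("list", n_scales * n_orientations)
  info <- vector("list", n_scales * n_orientations)
  orients <- (seq_len(n_orientations) - 1) * 180 / n_orientations
  idx <- 1L
  for (j in seq_len(n_scales) - 1L) {
    lambda <- 3 * 2^j
    sigma <- 0.56 * lambda
    base <- exp(-(x^2 + y^2) / (2 * sigma^2)) * cos(2 * pi * x / lambda)
    base <- unit_norm(base - mean(base))
    for (o in seq_along(orients)) {
      kk <- if (orients[o] == 0) base else rotate_kernel(base, orients[o])
      kk <- kk - mean(kk)
      kernels[[idx]] <- kk
      info[[idx]] <- tibble::tibble(
        family = "gabor", scale_index = j, orientation_deg = orients[o],
        rotation_index = 0L, source_id = sprintf("gabor_s%d_o%g", j, orients[o])
      )
      idx <- idx + 1L
    }
  }
  kernel_bank(kernels, dplyr::bind_rows(info),
              name = sprintf("gabor_%dx%d", n_scales, n_orientations),
              normalized = normalized)
}

#' Laplacian-of-Gaussian bank
#'
#' Isotropic center-surround kernels at `n_scales` scales,
#' `sigma_j = sigma0 * ratio^j`. The default scales keep the surround inside
#' the 9 x 9 support so the kernels remain rotationally symmetric on the
#' grid. Each kernel sums exactly to zero (zero DC) by construction.
#'
#' @param n_scales Number of scales (>= 1).
#' @param size Odd kernel side length (default 9).
#' @param sigma0 Smallest Gaussian scale in px.
#' @param ratio Scale ratio between consecutive kernels.
#' @param normalized Unit-normalize each kernel (default `TRUE`).
#' @return A `kernel_bank` of `n_scales` kernels.
#' @examples
#' log_bank(3)
#' @export
log_bank <- function(n_scales = 3, size = 9, sigma0 = 0.6, ratio = 1.5,
                     normalized = TRUE) {
  if (n_scales < 1) stop_invalid("n_scales must be >= 1")
  size <- check_odd_size(size)
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size) - c0, each = size), size, size)
  y <- matrix(rep(seq_len(size) - c0, times = size), size, size)
  r2 <- x^2 + y^2
  kernels <- vector("list", n_scales)
  info <- vector("list", n_scales)
  for (j in seq_len(n_scales) - 1L) {
    sigma <- sigma0 * ratio^j
    kk <- -(1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
    kk <- kk - mean(kk)  # exact zero DC on the discrete grid
    kernels[[j + 1L]] <- kk
    info[[j + 1L]] <- tibble::tibble(
      family = "log", scale_index = j, orientation_deg = NA_real_,
      rotation_index = 0L, source_id = sprintf("log_s%d", j)
    )
  }
  kernel_bank(kernels, dplyr::bind_rows(info),
              name = sprintf("log_%d", n_scales), normalized = normalized)
}

#' Rotational expansion of a bank
#'
#' Expands every kernel into `n_steps` rotated copies at multiples of
#' `step_deg` (bilinear resampling about the kernel center, out-of-support
#' samples 0). The default 8 steps of 45 degrees turn a 64-kernel dictionary
#' into 512 kernels for matching pursuit, allowing orientation steering of
#' the dictionary. Output order is kernel-major, rotation-minor, and
#' `rotation_index` records the step.
#'
#' @param bank A non-empty `kernel_bank`.
#' @param n_steps Number of rotation steps (>= 1; step 0 is the identity).
#' @param step_deg Rotation increment in degrees (default 45).
#' @return A `kernel_bank` with `length(bank) * n_steps` kernels.
#' @examples
#' length(rotate_expand(gabor_bank(2, 4), n_steps = 8))  # 64
#' @export
rotate_expand <- function(bank, n_steps = 8, step_deg = 45) {
  if (length(bank) == 0) stop_invalid("cannot expand an empty bank")
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  n <- length(bank)
  out <- vector("list", n * n_steps)
  info <- vector("list", n * n_steps)
  idx <- 1L
  for (i in seq_len(n)) {
    base <- bank$kernels[, , i]
    for (s in seq_len(n_steps) - 1L) {
      kk <- if (s == 0L) base else rotate_kernel(base, s * step_deg)
      if (bank$normalized) kk <- unit_norm(kk)
      out[[idx]] <- kk
      row <- bank$info[i, ]
      row$rotation_index <- s
      if (!is.na(row$orientation_deg)) {
        row$orientation_deg <- (row$orientation_deg + s * step_deg) %% 360
      }
      info[[idx]] <- row
      idx <- idx + 1L
    }
  }
  kernel_bank(out, dplyr::bind_rows(info),
              name = sprintf("%s_rot%d", bank$name, n_steps),
              normalized = bank$normalized)
}

#' Noise/redundancy filtering and seeded subsampling of a bank
#'
#' Reproduces the front-end selection pipeline: (1) discard kernels whose
#' high-spatial-frequency power fraction (power at radial frequency above
#' 0.25 cycles/px) exceeds `noise_cutoff` ("too noisy"); (2) greedily drop
#' the later member of any pair with absolute cosine similarity above
#' `similarity_cutoff` ("redundant"); (3) draw `n` of the survivors without
#' replacement under `seed`. The result preserves original bank order and is
#' deterministic given the seed.
#'
#' @param bank A `kernel_bank`.
#' @param n Number of kernels to select. `NULL` keeps all survivors.
#' @param noise_cutoff Maximum tolerated high-frequency power fraction.
#' @param similarity_cutoff Maximum tolerated |cosine similarity|.
#' @param seed Integer seed for the subsampling step.
#' @return A `kernel_bank` of `n` kernels; the `source_id` metadata is
#'   preserved so selections can be traced to the parent bank.
#' @export
select_subset <- function(bank, n = NULL, noise_cutoff = 0.5,
                          similarity_cutoff = 0.9, seed = 1) {
  nb <- length(bank)
  if (nb == 0) stop_invalid("cannot select from an empty bank")
  hf <- vapply(seq_len(nb), function(i) {
    high_freq_power_fraction(bank$kernels[, , i])
  }, 0)
  keep <- which(hf <= noise_cutoff)
  if (length(keep) > 1) {
    V <- bank_matrix(bank)[, keep, drop = FALSE]
    V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    retained <- 1L
    for (i in seq_along(keep)[-1]) {
      sims <- abs(crossprod(V[, retained, drop = FALSE], V[, i]))
      if (max(sims) <= similarity_cutoff) retained <- c(retained, i)
    }
    keep <- keep[retained]
  }
  n_surv <- length(keep)
  if (is.null(n)) n <- n_surv
  if (n > n_surv) {
    stop(errorCondition(
      sprintf("requested %d kernels but only %d survive filtering", n, n_surv),
      class = c("rfpursuit_infeasible_selection", "error")
    ))
  }
  sel <- if (n == n_surv) keep else sort(with_seed(seed, sample(keep, n)))
  out <- bank[sel]
  out$name <- sprintf("%s_sub%d", bank$name, n)
  out
}

#' Concatenate two kernel banks
#'
#' Kernels of `a` followed by kernels of `b`; both banks must share one
#' kernel side length. Used e.g. to append Laplacian-of-Gaussian channels to
#' a Gabor front-end.
#'
#' @param a,b `kernel_bank` objects with equal kernel side.
#' @return A `kernel_bank` of `length(a) + length(b)` kernels.
#' @export
concat_banks <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  if (kernel_side(a) != kernel_side(b)) {
    stop_invalid("kernel sides differ: ", kernel_side(a), " vs ", kernel_side(b))
  }
  k <- kernel_side(a)
  kernels <- array(c(a$kernels, b$kernels), dim = c(k, k, length(a) + length(b)))
  kernel_bank(kernels, dplyr::bind_rows(a$info, b$info),
              name = paste(a$name, b$name, sep = "+"),
              normalized = a$normalized && b$normalized)
}

#' Aggregated power spectrum of a bank
#'
#' Zero-pads every kernel to `pad_to x pad_to`, takes the 2-D DFT, and sums
#' squared magnitudes over kernels. The result is returned centered (DC in
#' the middle) for display; it is nonnegative everywhere and satisfies the
#' Parseval identity `sum(spectrum) == pad_to^2 * sum(kernel energies)`.
#'
#' @param bank A non-empty `kernel_bank`.
#' @param pad_to Output side length (>= kernel side).
#' @return A `pad_to x pad_to` numeric matrix.
#' @export
aggregate_power_spectrum <- function(bank, pad_to = 64) {
  if (length(bank) == 0) stop_invalid("cannot compute the spectrum of an empty bank")
  k <- kernel_side(bank)
  if (pad_to < k) stop_invalid("pad_to must be >= kernel side")
  acc <- matrix(0, pad_to, pad_to)
  for (i in seq_len(length(bank))) {
    padded <- matrix(0, pad_to, pad_to)
    padded[seq_len(k), seq_len(k)] <- bank$kernels[, , i]
    acc <- acc + Mod(stats::fft(padded))^2
  }
  fftshift2(acc)
}

# Center the DC bin of an unshifted 2-D spectrum (DC lands at
# floor(s/2) + 1 in both axes).
fftshift2 <- function(m) {
  s <- nrow(m)
  h <- ceiling(s / 2)
  idx <- c(seq(h + 1L, s), seq_len(h))
  m[idx, idx]
}

#' Radial profile of a centered 2-D spectrum
#'
#' Averages a centered spectrum over annuli of radial frequency, returning a
#' tibble of (frequency, power). Used for spectral-overlap diagnostics
#' between kernel families.
#'
#' @param spectrum A centered square spectrum (e.g. from
#'   [aggregate_power_spectrum()]).
#' @param n_bins Number of radial bins.
#' @return A tibble with columns `freq` (cycles/px) and `power`.
#' @export
radial_profile <- function(spectrum, n_bins = 20) {
  s <- nrow(spectrum)
  c0 <- floor(s / 2) + 1L
  x <- matrix(rep(seq_len(s) - c0, each = s), s, s)
  y <- matrix(rep(seq_len(s) - c0, times = s), s, s)
  r <- sqrt(x^2 + y^2) / s  # cycles per px
  bins <- cut(r, breaks = seq(0, 0.5 + 1e-9, length.out = n_bins + 1),
              include.lowest = TRUE)
  ok <- !is.na(bins)
  pw <- tapply(spectrum[ok], bins[ok], mean)
  pw[is.na(pw)] <- 0
  tibble::tibble(
    freq = seq(0, 0.5, length.out = n_bins + 1)[-1] - 0.25 / n_bins,
    power = as.numeric(pw)
  )
}

#' Overlap coefficient between two radial spectral profiles
#'
#' Normalizes both profiles to unit sum and returns the sum of bin-wise
#' minima (1 = identical support, 0 = disjoint).
#'
#' @param a,b Banks or centered spectra of equal size.
#' @param pad_to Padding used when banks are given.
#' @return Overlap coefficient in \[0, 1\].
#' @export
spectral_overlap <- function(a, b, pad_to = 64) {
  sp <- function(x) {
    if (inherits(x, "kernel_bank")) x <- aggregate_power_spectrum(x, pad_to)
    p <- radial_profile(x)$power
    p / sum(p)
  }
  sum(pmin(sp(a), sp(b)))
}
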