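# Synthetic study inputs: Gaussian white-noise stimuli, binary pattern
# stimuli rendered from parametric prototypes, linear-nonlinear neurons with
# signal-dependent noise, stimulus preprocessing, and the responsive-neuron
# filter.

#' Stimulus sets
#'
#' A stimulus set bundles a stack of equally sized grayscale images with an
#' optional per-stimulus label tibble (category, orientation, scale).
#'
#' @param images A `side x side x n` array.
#' @param labels Optional tibble with one row per stimulus.
#' @return A `stimulus_set`.
#' @export
stimulus_set <- function(images, labels = NULL) {
  if (length(dim(images)) != 3L || dim(images)[1] != dim(images)[2]) {
    stop_invalid("images must be a side x side x n array")
  }
  if (!all(is.finite(images))) stop_invalid("stimuli must be finite")
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    if (nrow(labels) != dim(images)[3]) {
      stop_invalid("labels must have one row per stimulus")
    }
  }
  structure(list(images = images, labels = labels), class = "stimulus_set")
}

#' @export
length.stimulus_set <- function(x) dim(x$images)[3]

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set>: %d stimuli of %dx%d px%s\n", length(x),
              stimulus_side(x), stimulus_side(x),
              if (is.null(x$labels)) "" else ", labeled"))
  invisible(x)
}

#' @export
`[.stimulus_set` <- function(x, i) {
  i <- seq_len(length(x))[i]
  stimulus_set(x$images[, , i, drop = FALSE],
               if (is.null(x$labels)) NULL else x$labels[i, ])
}

#' Stimulus side length
#' @param x A `stimulus_set`.
#' @return Integer side in px.
#' @export
stimulus_side <- function(x) dim(x$images)[1]

#' Stimuli as an `n x side^2` matrix (rows are vectorized images)
#' @param x A `stimulus_set`.
#' @return Numeric matrix.
#' @export
stimulus_matrix <- function(x) stack_to_matrix(x$images)

#' Gaussian white-noise stimuli
#'
#' Independent standard-normal pixels; the classical system-identification
#' stimulus ensemble. Deterministic given `seed`.
#'
#' @param n Number of stimuli.
#' @param side Image side in px (default 20).
#' @param seed Integer seed.
#' @return A `stimulus_set`.
#' @examples
#' s <- gaussian_noise_stimuli(100, 20, seed = 1)
#' @export
gaussian_noise_stimuli <- function(n, side = 20, seed = 1) {
  if (n < 1) stop_invalid("n must be >= 1")
  imgs <- with_seed(seed, array(stats::rnorm(side * side * n), dim = c(side, side, n)))
  stimulus_set(imgs)
}

#' Construct a linear-nonlinear synthetic neuron
#'
#' The neuron's receptive-field set is `k` small filters chosen (seeded)
#' from a kernel bank or from random crops of pattern stimuli, each
#' zero-padded into a `stimulus_side` canvas (centered by default, or at
#' seeded random placements). Responses follow the rectified
#' linear-nonlinear rule of [simulate_responses()].
#'
#' @param source A `kernel_bank` or a `stimulus_set` to crop RF patches
#'   from.
#' @param k Number of receptive-field filters (>= 1).
#' @param stimulus_side Canvas side in px (default 20).
#' @param seed Integer seed controlling selection and placement.
#' @param placement `"center"` (default) or `"random"`.
#' @param rf_side Patch side when cropping from stimuli (default 9).
#' @return A `synthetic_neuron`: list with `rfs` (list of padded matrices),
#'   `noise_scale`, `seed`, and `source_index` (indices into the bank, when
#'   a bank was given).
#' @export
make_synthetic_neuron <- function(source, k = 1, stimulus_side = 20, seed = 1,
                                  placement = c("center", "random"),
                                  rf_side = 9) {
  placement <- match.arg(placement)
  if (k < 1) stop_invalid("k must be >= 1")
  with_seed(seed, {
    if (inherits(source, "kernel_bank")) {
      if (k > length(source)) stop_invalid("k exceeds the bank size")
      idx <- sort(sample.int(length(source), k))
      filters <- lapply(idx, function(i) source$kernels[, , i])
    } else if (inherits(source, "stimulus_set")) {
      side <- stimulus_side(source)
      if (rf_side > side) stop_invalid("rf_side exceeds the stimulus side")
      idx <- sample.int(length(source), k, replace = k > length(source))
      filters <- lapply(idx, function(i) {
        r0 <- sample.int(side - rf_side + 1L, 1)
        c0 <- sample.int(side - rf_side + 1L, 1)
        unit_norm(source$images[r0:(r0 + rf_side - 1L), c0:(c0 + rf_side - 1L), i])
      })
    } else {
      stop_invalid("source must be a kernel_bank or stimulus_set")
    }
    d <- nrow(filters[[1]])
    if (d > stimulus_side) stop_invalid("RF filters larger than the stimulus canvas")
    rfs <- lapply(filters, function(f) {
      canvas <- matrix(0, stimulus_side, stimulus_side)
      off <- if (placement == "center") {
        rep(floor((stimulus_side - d) / 2) + 1L, 2L)
      } else {
        c(sample.int(stimulus_side - d + 1L, 1), sample.int(stimulus_side - d + 1L, 1))
      }
      canvas[off[1]:(off[1] + d - 1L), off[2]:(off[2] + d - 1L)] <- f
      canvas
    })
    structure(list(rfs = rfs, noise_scale = 0.1, seed = seed,
                   source_index = idx),
              class = "synthetic_neuron")
  })
}

#' Simulate linear-nonlinear responses
#'
#' The noiseless drive of stimulus `I` is `sum_s ReLU(I . s)` over the
#' neuron's padded receptive fields `s`. With `noise = TRUE`, Gaussian noise
#' with zero mean and variance `max(drive, 1e-6) * noise_scale` is added:
#' signal-dependent noise whose variance is one tenth of the drive at the
#' default `noise_scale = 0.1`. (For a single RF with positive drive this
#' equals drive/10; the max(. , 1e-6) floor keeps the variance defined when
#' the rectified drive is 0.)
#'
#' @param neuron A `synthetic_neuron`.
#' @param stimuli A `stimulus_set` with matching side.
#' @param noise Add noise? (default `TRUE`).
#' @param seed Integer seed for the noise draw.
#' @return Numeric response vector, one entry per stimulus.
#' @export
simulate_responses <- function(neuron, stimuli, noise = TRUE, seed = 1) {
  side <- stimulus_side(stimuli)
  if (nrow(neuron$rfs[[1]]) != side) {
    stop_invalid("stimulus side does not match the neuron's canvas")
  }
  X <- stimulus_matrix(stimuli)
  RF <- vapply(neuron$rfs, as.numeric, numeric(side * side))
  drive <- rowSums(pmax(X %*% RF, 0))
  if (!noise) return(drive)
  sd_i <- sqrt(pmax(drive, 1e-6) * neuron$noise_scale)
  drive + with_seed(seed, stats::rnorm(length(drive))) * sd_i
}

# --- binary pattern stimuli ---------------------------------------------------

#' Binary pattern stimuli from parametric prototypes
#'
#' Renders black-and-white pattern images from parametric prototypes in five
#' families -- oriented bars and gratings, curvature patterns (arcs, solid
#' disks, concentric rings), corners, crosses, and two-element compositions
#' -- at evenly spaced rotations and a geometric range of scales. This
#' emulates the design of composite pattern stimulus sets used to probe
#' higher-order selectivity; it is an emulation, not a reproduction of any
#' specific published stimulus set. Rotation is applied to the underlying
#' continuous shape before rasterization, so images stay exactly binary.
#'
#' @param categories Character vector drawn from `"bar"`, `"grating"`,
#'   `"curve"`, `"corner"`, `"cross"`, `"composition"`.
#' @param n_orientations Rotations per prototype, evenly spaced on
#'   \[0, 360).
#' @param n_scales Scales per prototype (geometric steps of 1.5x).
#' @param side Canvas side in px (>= 20).
#' @param seed Integer seed (placement jitter of composition elements).
#' @return A `stimulus_set` with labels `stimulus_id`, `category`,
#'   `prototype`, `orientation_deg`, `scale`.
#' @examples
#' ps <- generate_pattern_stimuli(c("bar", "cross"), 4, 1, side = 40)
#' table(ps$labels$category)
#' @export
generate_pattern_stimuli <- function(categories = c("bar", "grating", "curve",
                                                    "corner", "cross",
                                                    "composition"),
                                     n_orientations = 8, n_scales = 2,
                                     side = 40, seed = 1) {
  known <- c("bar", "grating", "curve", "corner", "cross", "composition")
  bad <- setdiff(categories, known)
  if (length(bad)) stop_invalid("unknown categories: ", paste(bad, collapse = ", "))
  if (side < 20) stop_invalid("side must be >= 20")
  protos <- pattern_prototypes()
  protos <- protos[vapply(protos, function(p) p$category %in% categories, TRUE)]
  orients <- (seq_len(n_orientations) - 1) * 360 / n_orientations
  scales <- 1.5^(seq_len(n_scales) - 1)
  n_total <- length(protos) * n_orientations * n_scales
  imgs <- array(0, dim = c(side, side, n_total))
  labels <- vector("list", n_total)
  c0 <- (side + 1) / 2
  xg <- matrix(rep(seq_len(side) - c0, each = side), side, side)
  yg <- matrix(rep(seq_len(side) - c0, times = side), side, side)
  i <- 1L
  with_seed(seed, {
    for (p in protos) for (sc in scales) for (th in orients) {
      # rotate the coordinate frame before rasterizing; cospi/sinpi keep
      # axis-aligned rotations exact so e.g. the 90-degree bar is a perfect
      # transpose of the 0-degree bar
      ct <- cospi(-th / 180)
      st <- sinpi(-th / 180)
      u <- (ct * xg + st * yg) / (sc * side / 40)
      v <- (-st * xg + ct * yg) / (sc * side / 40)
      imgs[, , i] <- p$mask(u, v) * 1
      labels[[i]] <- tibble::tibble(
        stimulus_id = i, category = p$category, prototype = p$name,
        orientation_deg = th, scale = sc
      )
      i <- i + 1L
    }
  })
  stimulus_set(imgs, dplyr::bind_rows(labels))
}

# Prototype shape masks in a canonical frame (units: px of a 40 px canvas,
# origin at the canvas center). Each returns a logical mask.
pattern_prototypes <- function() {
  bar <- function(len, wid) function(u, v) abs(u) <= len / 2 & abs(v) <= wid / 2
  grating <- function(period, wid) function(u, v) {
    abs(u) <= 16 & abs(v) <= 16 & (floor(v / (period / 2)) %% 2 == 0)
  }
  arc <- function(r, wid, span) function(u, v) {
    rr <- sqrt(u^2 + v^2)
    ang <- atan2(v, u)
    abs(rr - r) <= wid / 2 & abs(ang) <= span / 2
  }
  disk <- function(r) function(u, v) u^2 + v^2 <= r^2
  ring <- function(r, wid) function(u, v) abs(sqrt(u^2 + v^2) - r) <= wid / 2
  corner <- function(len, wid, ang) function(u, v) {
    a1 <- abs(u) <= len / 2 & abs(v) <= wid / 2 & u >= 0
    th <- ang * pi / 180
    u2 <- cos(th) * u + sin(th) * v
    v2 <- -sin(th) * u + cos(th) * v
    a2 <- abs(u2) <= len / 2 & abs(v2) <= wid / 2 & u2 >= 0
    a1 | a2
  }
  cross <- function(len, wid, ang) function(u, v) {
    a1 <- abs(u) <= len / 2 & abs(v) <= wid / 2
    th <- ang * pi / 180
    u2 <- cos(th) * u + sin(th) * v
    v2 <- -sin(th) * u + cos(th) * v
    a2 <- abs(u2) <= len / 2 & abs(v2) <= wid / 2
    a1 | a2
  }
  compose <- function(f1, f2, dx) function(u, v) f1(u + dx, v) | f2(u - dx, v)
  list(
    list(name = "bar_long_thin", category = "bar", mask = bar(24, 3)),
    list(name = "bar_long_thick", category = "bar", mask = bar(24, 6)),
    list(name = "bar_short_thin", category = "bar", mask = bar(12, 3)),
    list(name = "bar_short_thick", category = "bar", mask = bar(12, 6)),
    list(name = "grating_fine", category = "grating", mask = grating(8, 32)),
    list(name = "grating_coarse", category = "grating", mask = grating(16, 32)),
    list(name = "arc_open", category = "curve", mask = arc(9, 3, pi)),
    list(name = "arc_tight", category = "curve", mask = arc(6, 3, 1.5 * pi)),
    list(name = "disk_small", category = "curve", mask = disk(5)),
    list(name = "ring_mid", category = "curve", mask = ring(8, 3)),
    list(name = "corner_right", category = "corner", mask = corner(16, 3, 90)),
    list(name = "corner_acute", category = "corner", mask = corner(16, 3, 45)),
    list(name = "corner_obtuse", category = "corner", mask = corner(16, 3, 135)),
    list(name = "cross_right", category = "cross", mask = cross(20, 3, 90)),
    list(name = "cross_oblique", category = "cross", mask = cross(20, 3, 45)),
    list(name = "comp_bar_disk", category = "composition",
         mask = compose(bar(12, 3), disk(4), 8)),
    list(name = "comp_bar_bar", category = "composition",
         mask = compose(bar(12, 3), bar(12, 6), 7)),
    list(name = "comp_arc_bar", category = "composition",
         mask = compose(arc(6, 3, pi), bar(10, 3), 8))
  )
}

#' Center-crop and area-average downscale a stimulus
#'
#' Crops the central `crop_side` pixels, then downscales to
#' `out_side x out_side` by averaging equal square blocks (`crop_side` must
#' be a multiple of `out_side`). Constant images map to the same constant.
#'
#' @param image A square numeric matrix.
#' @param crop_side Central crop side (default 40), at most the image side.
#' @param out_side Output side (default 20), at most `crop_side`.
#' @return An `out_side x out_side` matrix.
#' @examples
#' img <- matrix(runif(90 * 90), 90, 90)
#' dim(preprocess_stimulus(img, 40, 20))
#' @export
preprocess_stimulus <- function(image, crop_side = 40, out_side = 20) {
  s <- nrow(image)
  if (ncol(image) != s) stop_invalid("image must be square")
  if (crop_side > s || out_side > crop_side) {
    stop_invalid("need out_side <= crop_side <= image side")
  }
  if (crop_side %% out_side != 0) {
    stop_invalid("crop_side must be a multiple of out_side for block averaging")
  }
  off <- floor((s - crop_side) / 2)
  crop <- image[off + seq_len(crop_side), off + seq_len(crop_side)]
  b <- crop_side / out_side
  # block means via row/column aggregation
  rowagg <- rowsum(crop, rep(seq_len(out_side), each = b))
  out <- t(rowsum(t(rowagg), rep(seq_len(out_side), each = b))) / b^2
  dimnames(out) <- NULL
  out
}

#' Preprocess every stimulus in a set
#'
#' @param stimuli A `stimulus_set`.
#' @inheritParams preprocess_stimulus
#' @return A `stimulus_set` of `out_side`-sided images with labels carried
#'   over.
#' @export
preprocess_stimuli <- function(stimuli, crop_side = 40, out_side = 20) {
  n <- length(stimuli)
  out <- array(0, dim = c(out_side, out_side, n))
  for (i in seq_len(n)) {
    out[, , i] <- preprocess_stimulus(stimuli$images[, , i], crop_side, out_side)
  }
  stimulus_set(out, stimuli$labels)
}

#' Keep neurons with enough supra-threshold responses
#'
#' A neuron is kept iff it has at least `min_count` stimuli with response
#' strictly greater than `threshold` (the screening rule that removes
#' neurons without significant stimulus preference before model fitting).
#'
#' @param responses A stimuli x neurons matrix or data frame of responses.
#' @param threshold Response threshold (default 0.2).
#' @param min_count Minimum number of supra-threshold stimuli (default 50).
#' @return A tibble with columns `neuron`, `n_above`, `keep`.
#' @examples
#' resp <- cbind(a = c(rep(0.3, 50), rep(0, 50)), b = rep(0.1, 100))
#' filter_responsive_neurons(resp, 0.2, 50)
#' @export
filter_responsive_neurons <- function(responses, threshold = 0.2, min_count = 50) {
  m <- as.matrix(responses)
  if (!all(is.finite(m))) stop_invalid("responses must be finite")
  n_above <- colSums(m > threshold)
  tibble::tibble(
    neuron = if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m),
    n_above = as.integer(n_above),
    keep = n_above >= min_count
  )
}

#' Seeded train/validation/test split
#'
#' Shuffles stimulus indices under `seed` and splits them 60/20/20 by
#' default (test fraction matching the held-out ratio used for tuning-curve
#' evaluation).
#'
#' @param n Number of stimuli.
#' @param fractions Length-3 numeric vector summing to 1.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop_invalid("fractions must be three numbers summing to 1")
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1L):n])
}
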