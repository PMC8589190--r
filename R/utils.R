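# Internal numerical utilities shared across modules: seeded evaluation,
# bilinear rotation resampling, and sparse im2col/col2im operators that turn
# 2-D valid cross-correlation (and its adjoint, full convolution) into
# BLAS-backed matrix products.

#' @importFrom Matrix sparseMatrix t
#' @importFrom stats rnorm runif sd quantile coef lm optim fft
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rfpursuit_invalid_argument", "error")))
}

check_odd_size <- function(size, min = 3L) {
  if (length(size) != 1L || !is.finite(size) || size < min || size %% 2L != 1L) {
    stop_invalid("kernel size must be an odd integer >= ", min, ", got ", size)
  }
  as.integer(size)
}

# Rotate a square matrix by `deg` degrees (counter-clockwise in standard x/y
# axes) about its center, resampling bilinearly; samples falling outside the
# original support are 0.
rotate_kernel <- function(m, deg) {
  k <- nrow(m)
  if (ncol(m) != k) stop_invalid("rotate_kernel() needs a square matrix")
  theta <- deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  c0 <- (k + 1) / 2
  # output grid (row i -> y, col j -> x), centered coordinates
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  x <- idx$j - c0
  y <- idx$i - c0
  # inverse rotation of the sampling grid
  xs <- ct * x + st * y + c0
  ys <- -st * x + ct * y + c0
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(length(xs))
  sample_at <- function(r, c) {
    ok <- r >= 1 & r <= k & c >= 1 & c <= k
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  val <- (1 - fx) * (1 - fy) * sample_at(y0, x0) +
    fx * (1 - fy) * sample_at(y0, x0 + 1) +
    (1 - fx) * fy * sample_at(y0 + 1, x0) +
    fx * fy * sample_at(y0 + 1, x0 + 1)
  matrix(val, k, k)
}

l2norm <- function(x) sqrt(sum(x^2))

unit_norm <- function(m) {
  n <- l2norm(m)
  if (n == 0) m else m / n
}

# --- im2col / col2im machinery ------------------------------------------------

# Sparse operator for k x k sliding windows over h x w images (stride 1,
# "valid"). For images flattened column-major into rows of X (n x h*w):
#   G <- as.matrix(X %*% Matrix::t(op$S))      # n x (n_pos * k2)
# has columns ordered position-fastest, element-slowest, so
#   dim(G) <- c(n * n_pos, k2); G %*% K        # K: k2 x C
# is the valid cross-correlation of every image with every kernel column.
# The transpose direction implements the adjoint (zero-padded full
# convolution of coefficient maps with the kernels).
make_conv_op <- function(h, w = h, k) {
  oh <- h - k + 1L
  ow <- w - k + 1L
  if (oh < 1L || ow < 1L) stop_invalid("kernel (", k, ") larger than image (", h, "x", w, ")")
  n_pos <- oh * ow
  k2 <- k * k
  pr <- rep(seq_len(oh), times = ow)           # position row, column-major
  pc <- rep(seq_len(ow), each = oh)
  er <- rep(seq_len(k), times = k)             # element row within window
  ec <- rep(seq_len(k), each = k)
  # rows: (e-1)*n_pos + p ; cols: pixel linear index
  p_idx <- rep(seq_len(n_pos), times = k2)
  e_idx <- rep(seq_len(k2), each = n_pos)
  row <- (e_idx - 1L) * n_pos + p_idx
  pixr <- pr[p_idx] + er[e_idx] - 1L
  pixc <- pc[p_idx] + ec[e_idx] - 1L
  col <- (pixc - 1L) * h + pixr
  S <- Matrix::sparseMatrix(i = row, j = col, x = 1, dims = c(n_pos * k2, h * w))
  list(S = S, St = Matrix::t(S), h = h, w = w, k = k, oh = oh, ow = ow,
       n_pos = n_pos, k2 = k2)
}

# X: n x (h*w); K: k2 x C. Returns (n * n_pos) x C response matrix (rows:
# image-fastest, then position).
conv_corr_valid <- function(op, X, K) {
  G <- as.matrix(X %*% op$St)
  dim(G) <- c(nrow(X) * op$n_pos, op$k2)
  G %*% K
}

# R_mat: (n * n_pos) x C coefficient maps; K: k2 x C. Returns n x (h*w)
# reconstruction Sum_c conv_full(coeff_c, kernel_c).
conv_adjoint <- function(op, R_mat, K) {
  n <- nrow(R_mat) / op$n_pos
  tmp <- R_mat %*% t(K)                        # (n*n_pos) x k2
  dim(tmp) <- c(n, op$n_pos * op$k2)
  as.matrix(tmp %*% op$S)
}

# Gradient of the correlation responses w.r.t. the kernels given upstream
# gradients D ((n*n_pos) x C) and images X: returns k2 x C.
conv_kernel_grad <- function(op, X, D) {
  G <- as.matrix(X %*% op$St)
  dim(G) <- c(nrow(X) * op$n_pos, op$k2)
  t(G) %*% D
}

# Flatten a stack of images (h x w x n array) into an n x (h*w) matrix,
# pixels column-major, and back.
stack_to_matrix <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(3L, 1L, 2L)), d[3L], d[1L] * d[2L])
}

matrix_to_stack <- function(m, h, w = h) {
  n <- nrow(m)
  aperm(array(m, dim = c(n, h, w)), c(2L, 3L, 1L))
}

# Radial frequency grid (cycles/px) for an s x s DFT, unshifted layout.
fft_radial_freq <- function(s) {
  f <- c(seq(0L, floor(s / 2)), seq(-ceiling(s / 2) + 1L, -1L)) / s
  fx <- matrix(rep(f, each = s), s, s)
  fy <- matrix(rep(f, times = s), s, s)
  sqrt(fx^2 + fy^2)
}

# Fraction of a kernel's spectral power above `cutoff` cycles/px.
high_freq_power_fraction <- function(m, cutoff = 0.25) {
  s <- nrow(m)
  P <- Mod(stats::fft(m))^2
  tot <- sum(P)
  if (tot == 0) return(0)
  sum(P[fft_radial_freq(s) > cutoff]) / tot
}
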