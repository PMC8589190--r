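test_that("pooled features match a brute-force position scan exactly", {
  with_seed_test(42, {
    for (case in 1:100) {
      w <- sample(10:14, 1)
      d <- sample(3:5, 1)
      img <- matrix(rnorm(w * w), w, w)
      k <- matrix(rnorm(d * d), d, d)
      bf <- -Inf
      for (r in 1:(w - d + 1)) {
        for (c in 1:(w - d + 1)) {
          bf <- max(bf, abs(sum(img[r:(r + d - 1), c:(c + d - 1)] * k)))
        }
      }
      expect_identical(pooled_feature(k, img, "cppr"), bf)
    }
  })
})

test_that("pooled features reduce to dot products and autocorrelation peaks", {
  img <- with_seed_test(1, matrix(rnorm(100), 10, 10))
  k_full <- with_seed_test(2, matrix(rnorm(100), 10, 10))
  expect_equal(pooled_feature(k_full, img, "ppr"), sum(img * k_full))
  # cppr with kernel side = image side pools over a single position
  expect_equal(pooled_feature(k_full, img, "cppr"), abs(sum(img * k_full)))

  imp <- matrix(0, 3, 3); imp[2, 2] <- 1
  expect_equal(pooled_feature(imp, img, "cppr"), max(abs(img[2:9, 2:9])))

  kern <- with_seed_test(3, matrix(rnorm(25), 5, 5))
  kern <- kern / sqrt(sum(kern^2))
  embedded <- matrix(0, 15, 15)
  embedded[6:10, 6:10] <- kern
  expect_equal(pooled_feature(kern, embedded, "cppr"), 1, tolerance = 1e-6)

  expect_error(pooled_feature(matrix(0, 12, 12), img, "cppr"),
               class = "rfpursuit_invalid_argument")
})

test_that("quadratic link fits are normal-equation optima", {
  l <- fit_quadratic_link(c(-1, 0, 1), c(1, 0, 1))
  expect_equal(c(l$a, l$b, l$c), c(1, 0, 0), tolerance = 1e-12)

  l2 <- fit_quadratic_link(c(0, 1, 2, 5), rep(5, 4))
  expect_equal(c(l2$a, l2$b, l2$c), c(0, 0, 5), tolerance = 1e-12)

  with_seed_test(7, {
    z <- rnorm(50); r <- rnorm(50)
    fit <- fit_quadratic_link(z, r)
    oracle <- qr.solve(cbind(z^2, z, 1), r)
    expect_equal(c(fit$a, fit$b, fit$c), unname(oracle), tolerance = 1e-8)
    # no other coefficients give lower SSE (perturbation check)
    sse <- function(cf) sum((r - cf[1] * z^2 - cf[2] * z - cf[3])^2)
    base <- sse(c(fit$a, fit$b, fit$c))
    for (i in 1:10) {
      expect_gte(sse(c(fit$a, fit$b, fit$c) + rnorm(3, sd = 0.01)), base)
    }
  })

  expect_error(fit_quadratic_link(rep(2, 10), rnorm(10)),
               class = "rfpursuit_rank_deficient")
})

test_that("pursuit contributions follow the variance-explained formula", {
  lk <- function(a, b, c) structure(list(a = a, b = b, c = c),
                                    class = "quadratic_link")
  z <- c(-1, 0, 1); r <- c(1, 0, 1)
  expect_equal(pursuit_contribution(lk(1, 0, 0), z, r), 1)
  expect_equal(pursuit_contribution(lk(0, 0, 0), z, r), 0)
  expect_equal(pursuit_contribution(lk(0, 0.5, 0), c(2, 0), c(2, 0)), 0.75)
  expect_error(pursuit_contribution(lk(1, 1, 1), z, c(0, 0, 0)),
               class = "rfpursuit_undefined_contribution")
})

test_that("cmpr recovers a dictionary receptive field from white noise", {
  bank <- gabor_bank(3, 8, 9)
  stim <- gaussian_noise_stimuli(6000, 20, seed = 700)
  cache <- pursuit_feature_cache(stim, "cmpr", dictionary = bank)
  hits <- 0
  for (draw in 1:10) {
    neuron <- make_synthetic_neuron(bank, 1, 20, seed = 600 + draw)
    y <- simulate_responses(neuron, stim, noise = FALSE)
    m <- fit_pursuit(stim, y, M = 1, mode = "cmpr", dictionary = bank,
                     cache = cache)
    j_hat <- m$stages[[1]]$dict_index
    j_true <- neuron$source_index
    # exact recovery, or a kernel whose pooled features are nearly
    # collinear with the true kernel's
    if (j_hat == j_true ||
        stats::cor(cache$Zd[, j_true], cache$Zd[, j_hat]) > 0.95) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("cmpr stage selection equals independent exhaustive enumeration", {
  bank <- gabor_bank(2, 4, 9)
  fx <- fixture_single_rf(n_train = 200, bank = bank, seed = 801)
  m <- fit_pursuit(fx$train, fx$y_train, M = 2, mode = "cmpr",
                   dictionary = bank, reduce = FALSE)
  # recompute stage 1 by brute force: every kernel, closed-form link fit
  X <- stimulus_matrix(fx$train)
  Z <- vapply(seq_len(length(bank)), function(j) {
    vapply(seq_len(200), function(i) {
      pooled_feature(bank$kernels[, , j], matrix(X[i, ], 20, 20), "cmpr")
    }, 0)
  }, numeric(200))
  r <- fx$y_train
  Is <- vapply(seq_len(ncol(Z)), function(j) {
    l <- fit_quadratic_link(Z[, j], r)
    pursuit_contribution(l, Z[, j], r)
  }, 0)
  expect_equal(m$stages[[1]]$dict_index, which.max(Is))
  expect_equal(m$stages[[1]]$contribution, max(Is), tolerance = 1e-10)
})

test_that("pursuit structure: empty models, monotone residuals, additivity", {
  fx <- fixture_single_rf(n_train = 150, seed = 901)
  m0 <- fit_pursuit(fx$train, fx$y_train, M = 0, mode = "cmpr",
                    dictionary = fx$bank)
  expect_equal(length(m0$stages), 0)
  expect_equal(predict(m0, fx$test), numeric(length(fx$test)))

  # residual energy is non-increasing across accepted stages
  for (seed in 1:3) {
    fxr <- fixture_single_rf(n_train = 120, seed = 910 + seed)
    y <- fxr$y_train + with_seed_test(seed, rnorm(120, sd = 0.3))
    m <- fit_pursuit(fxr$train, y, M = 4, mode = "cmpr",
                     dictionary = fxr$bank, reduce = FALSE,
                     min_contribution = 1e-6)
    r <- y
    energies <- sum(r^2)
    for (st in m$stages) {
      r <- r - rfpursuit:::link_eval(st$link, st$z)
      energies <- c(energies, sum(r^2))
    }
    expect_true(all(diff(energies) <= 1e-8))
    expect_true(all(vapply(m$stages, `[[`, 0, "contribution") <= 1))
  }

  # predictions are sums of per-stage predictions
  m2 <- fit_pursuit(fx$train, fx$y_train, M = 2, mode = "cmpr",
                    dictionary = fx$bank, reduce = FALSE,
                    min_contribution = 1e-9)
  if (length(m2$stages) == 2) {
    m_a <- m2; m_a$stages <- m2$stages[1]
    m_b <- m2; m_b$stages <- m2$stages[2]
    expect_equal(predict(m2, fx$test),
                 predict(m_a, fx$test) + predict(m_b, fx$test),
                 tolerance = 1e-12)
  }

  expect_error(fit_pursuit(fx$train, rep(1, length(fx$train)), M = 1,
                           mode = "cmpr", dictionary = fx$bank),
               class = "rfpursuit_invalid_argument")
  expect_error(fit_pursuit(fx$train, fx$y_train, M = 1, mode = "cmpr"),
               class = "rfpursuit_invalid_argument")
})

test_that("gradient-based ppr stages find informative kernels", {
  fx <- fixture_single_rf(n_train = 1000, seed = 921)
  m_ppr <- fit_pursuit(fx$train, fx$y_train, M = 2, mode = "ppr",
                       restarts = 3, maxit = 120, seed = 3)
  r_ppr <- pearson(predict(m_ppr, fx$test), fx$y_test)
  expect_gt(r_ppr, 0.7)
  # the recovered first-stage kernel aligns with the true padded RF
  k1 <- as.numeric(m_ppr$stages[[1]]$kernel)
  rf <- as.numeric(fx$neuron$rfs[[1]])
  expect_gt(abs(sum(k1 * rf)) / sqrt(sum(k1^2) * sum(rf^2)), 0.8)
})

test_that("redundancy reduction drops duplicates but never the top stage", {
  fx <- fixture_single_rf(n_train = 200, seed = 931)
  m <- fit_pursuit(fx$train, fx$y_train, M = 1, mode = "cmpr",
                   dictionary = fx$bank, reduce = FALSE)
  st <- m$stages[[1]]
  m$stages <- list(st, st)  # two identical stages
  red <- reduce_redundant(m, fx$train, fx$y_train)
  expect_equal(length(red$stages), 1)

  m1 <- m; m1$stages <- list(st)
  red1 <- reduce_redundant(m1, fx$train, fx$y_train)
  expect_equal(length(red1$stages), 1)

  # variance explained never drops by more than epsilon per removed stage
  for (seed in 1:3) {
    fxr <- fixture_single_rf(n_train = 150, seed = 940 + seed)
    y <- fxr$y_train + with_seed_test(seed, rnorm(150, sd = 0.5))
    full <- fit_pursuit(fxr$train, y, M = 4, mode = "cmpr",
                        dictionary = fxr$bank, reduce = FALSE,
                        min_contribution = 1e-9)
    eps <- 0.01
    red <- reduce_redundant(full, fxr$train, y, epsilon = eps)
    ve <- function(mod) {
      pred <- predict(mod, fxr$train)
      1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    }
    n_drop <- length(full$stages) - length(red$stages)
    expect_gte(ve(red), ve(full) - eps * max(n_drop, 0) - 1e-8)
  }
})

test_that("convolutional pursuit models are far smaller than full-field ppr", {
  # per stage: d^2 + 3 vs w^2 + 3 learnable scalars
  d <- 9; w <- 20
  expect_lte(d^2 + 3, 0.25 * (w^2 + 3))
  fx <- fixture_single_rf(n_train = 150, seed = 951)
  m <- fit_pursuit(fx$train, fx$y_train, M = 1, mode = "cmpr",
                   dictionary = fx$bank)
  g <- glance(m)
  expect_equal(g$n_parameters, length(m$stages) * (81 + 3))
})
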