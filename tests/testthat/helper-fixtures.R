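# Shared fixtures, all generated in code. Expensive objects are memoized so
# the suite builds them once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# A small convolutional sparse-code bank learned from whitened dead-leaves
# images.
fixture_csc_bank <- function() {
  memo("csc_bank", {
    imgs <- whiten_images(generate_training_images(6, 64, "dead_leaves",
                                                   seed = 301))
    ps <- sample_patches(imgs, patch = 21, n = 250, seed = 302)
    cfg <- csc_config(n_channels = 16, kernel_size = 9, sparsity_weight = 0.05,
                      n_alternations = 5, coder_steps = 12, seed = 303)
    learn_csc_dictionary(ps, cfg)
  })
}

# A mixed 64-kernel bank for selection-pipeline tests: Gabors, LOGs, and
# smooth random kernels (low high-frequency power), plus a few pure-noise
# kernels that the noisiness filter should discard.
fixture_mixed_bank <- function() {
  memo("mixed_bank", {
    gb <- gabor_bank(3, 8, 9)
    lb <- log_bank(3, 9)
    smooth <- with_seed_test(401, {
      ks <- lapply(1:31, function(i) {
        m <- matrix(rnorm(81), 9, 9)
        # light smoothing keeps high-frequency power low
        sm <- matrix(0, 9, 9)
        for (r in 1:9) for (c in 1:9) {
          rr <- max(1, r - 1):min(9, r + 1)
          cc <- max(1, c - 1):min(9, c + 1)
          sm[r, c] <- mean(m[rr, cc])
        }
        sm
      })
      kernel_bank(ks, name = "smooth31")
    })
    noisy <- with_seed_test(402, {
      kernel_bank(lapply(1:6, function(i) matrix(rnorm(81), 9, 9)),
                  name = "noisy6")
    })
    concat_banks(concat_banks(gb, lb), concat_banks(smooth, noisy))
  })
}

# The 24-kernel complex-shaped front end: a 64-channel dictionary learned
# from whitened dead-leaves imagery, filtered and subsampled to 24 kernels
# (the fixed-kernel network's first layer at its parameter-parity size).
fixture_frontend_bank <- function() {
  memo("frontend_bank", {
    imgs <- whiten_images(generate_training_images(8, 96, "dead_leaves",
                                                   seed = 311))
    ps <- sample_patches(imgs, patch = 25, n = 250, seed = 312)
    csc64 <- learn_csc_dictionary(ps, csc_config(
      n_channels = 64, kernel_size = 9, sparsity_weight = 0.25,
      n_alternations = 4, coder_steps = 9, seed = 313
    ))
    select_subset(csc64, 24, noise_cutoff = 0.5, similarity_cutoff = 0.9,
                  seed = 314)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Quick single-RF synthetic problem: neuron, train and test stimuli.
fixture_single_rf <- function(n_train = 600, n_test = 300, bank = NULL,
                              seed = 501) {
  if (is.null(bank)) bank <- gabor_bank(2, 4, 9)
  neuron <- make_synthetic_neuron(bank, 1, 20, seed = seed)
  train <- gaussian_noise_stimuli(n_train, 20, seed = seed + 1)
  test <- gaussian_noise_stimuli(n_test, 20, seed = seed + 2)
  list(bank = bank, neuron = neuron, train = train, test = test,
       y_train = simulate_responses(neuron, train, noise = FALSE),
       y_test = simulate_responses(neuron, test, noise = FALSE))
}
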