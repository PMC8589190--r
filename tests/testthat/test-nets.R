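test_that("network construction follows the conv/pool geometry", {
  cfg9 <- net_config("cnn9")
  expect_equal(cfg9$conv_side, 12)  # 20 - 9 + 1
  expect_equal(cfg9$pooled_side, 4)
  net9 <- build_network(cfg9)
  expect_false(net9$first_layer_frozen)

  bank24 <- select_subset(fixture_mixed_bank(), 24, seed = 1)
  cfgf <- net_config("fixed", front_end = bank24)
  netf <- build_network(cfgf)
  expect_equal(cfgf$n_kernels, 24)
  expect_true(netf$first_layer_frozen)
  expect_identical(netf$W, bank_matrix(bank24))

  glcnn_bank <- concat_banks(gabor_bank(3, 8, 9), log_bank(3, 9))
  cfg_gl <- net_config("fixed", front_end = glcnn_bank)
  expect_equal(cfg_gl$n_kernels, 27)

  expect_error(net_config("fixed"), class = "rfpursuit_invalid_argument")
  expect_error(net_config("cnn4", pool_window = 5, pool_stride = 4),
               class = "rfpursuit_invalid_argument")
})

test_that("learnable parameter counts exclude frozen layers", {
  cfg4 <- net_config("cnn4")
  net4 <- build_network(cfg4)
  # hand count: conv 4*(81+1), readout 16 pooled positions * 4 channels + 1
  expect_equal(count_learnable_params(net4), 4 * 82 + 16 * 4 + 1)

  net9 <- build_network(net_config("cnn9"))
  expect_equal(count_learnable_params(net9), 9 * 82 + 16 * 9 + 1)
  expect_gt(count_learnable_params(net9), count_learnable_params(net4))

  bank24 <- select_subset(fixture_mixed_bank(), 24, seed = 1)
  netf <- build_network(net_config("fixed", front_end = bank24))
  expect_equal(count_learnable_params(netf), 16 * 24 + 1)  # conv contributes 0
  expect_lte(count_learnable_params(netf), count_learnable_params(net9))
})

test_that("forward pass equals a straight-line reimplementation", {
  bank <- gabor_bank(2, 3, 9)
  net <- build_network(net_config("fixed", front_end = bank, seed = 2))
  stim <- gaussian_noise_stimuli(10, 20, seed = 11)
  pred <- predict(net, stim)
  cfg <- net$config
  oracle <- vapply(1:10, function(i) {
    img <- stim$images[, , i]
    acc <- net$fc_b
    for (j in seq_len(cfg$n_kernels)) {
      k <- bank$kernels[, , j]
      conv <- matrix(0, 12, 12)
      for (r in 1:12) for (c in 1:12) {
        conv[r, c] <- max(0, sum(img[r:(r + 8), c:(c + 8)] * k))
      }
      pooled <- matrix(0, 4, 4)
      for (pr in 1:4) for (pc in 1:4) {
        pooled[pr, pc] <- max(conv[(pr - 1) * 3 + 1:3, (pc - 1) * 3 + 1:3])
      }
      acc <- acc + sum(pooled * matrix(net$fc_w[(j - 1) * 16 + 1:16], 4, 4))
    }
    acc
  }, 0)
  expect_equal(pred, oracle, tolerance = 1e-5)

  # all-zero stimulus: prediction is the readout bias
  zero <- stimulus_set(array(0, c(20, 20, 1)))
  expect_equal(predict(net, zero), net$fc_b)

  # elementwise map: permuting stimuli permutes predictions
  perm <- c(3, 1, 2, 10, 5, 4, 7, 6, 9, 8)
  expect_equal(predict(net, stim[perm]), pred[perm])
})

test_that("training is deterministic, freezes the front end, and approaches the readout optimum", {
  bank <- gabor_bank(2, 4, 9)
  fx <- fixture_single_rf(n_train = 1500, bank = bank, seed = 551)
  cfg <- net_config("fixed", front_end = bank, seed = 5)
  t1 <- train_network(build_network(cfg), fx$train, fx$y_train,
                      max_epochs = 250, patience = 250)
  t2 <- train_network(build_network(cfg), fx$train, fx$y_train,
                      max_epochs = 250, patience = 250)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$W, bank_matrix(bank))  # frozen layer untouched

  # for a frozen front end the model is linear in its pooled features, so
  # the closed-form least-squares readout bounds what training can reach
  nn <- build_network(cfg)
  ftr <- rfpursuit:::net_forward(nn, rfpursuit:::net_im2col(nn, stimulus_matrix(fx$train)),
                                 length(fx$train))$pooled
  fte <- rfpursuit:::net_forward(nn, rfpursuit:::net_im2col(nn, stimulus_matrix(fx$test)),
                                 length(fx$test))$pooled
  cf <- stats::lm.fit(cbind(1, ftr), fx$y_train)$coefficients
  cf[is.na(cf)] <- 0
  r_ceiling <- pearson(as.numeric(cbind(1, fte) %*% cf), fx$y_test)
  r_trained <- pearson(predict(t1, fx$test), fx$y_test)
  expect_gt(r_trained, r_ceiling - 0.1)

  expect_error(
    train_network(build_network(cfg), fx$train, rep(2, length(fx$train))),
    class = "rfpursuit_degenerate_target"
  )
})

test_that("learned variants update their kernels under training", {
  fx <- fixture_single_rf(n_train = 500, seed = 561)
  net <- build_network(net_config("cnn4", seed = 9))
  tr <- train_network(net, fx$train, fx$y_train, max_epochs = 30, patience = 30)
  expect_false(identical(tr$W, net$W))
  expect_equal(nrow(tr$history), 30)
  expect_false(tr$first_layer_frozen)
})

test_that("kernel importance silences all but one channel", {
  bank <- gabor_bank(2, 4, 9)
  fx <- fixture_single_rf(n_train = 400, bank = bank, seed = 571)
  net <- train_network(build_network(net_config("fixed", front_end = bank, seed = 3)),
                       fx$train, fx$y_train, max_epochs = 40, patience = 8)

  # construction: keep only channel 3's readout weights
  net3 <- net
  np <- net$config$pooled_side^2
  w <- net$fc_w * 0
  w[(3 - 1) * np + seq_len(np), 1] <- net$fc_w[(3 - 1) * np + seq_len(np), 1]
  net3$fc_w <- w
  imp <- kernel_importance(net3, fx$test, fx$y_test)
  full_r <- pearson(predict(net3, fx$test), fx$y_test, warn = FALSE)
  expect_equal(imp$importance[3], full_r)
  expect_true(all(imp$importance[-3] == 0))

  # permutation equivariance: relabeling channels relabels scores
  imp_full <- kernel_importance(net, fx$test, fx$y_test)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  bank_p <- bank[perm]
  net_p <- build_network(net_config("fixed", front_end = bank_p, seed = 3))
  net_p$fc_b <- net$fc_b
  for (newj in seq_along(perm)) {
    oldj <- perm[newj]
    net_p$fc_w[(newj - 1) * np + seq_len(np), 1] <-
      net$fc_w[(oldj - 1) * np + seq_len(np), 1]
  }
  imp_p <- kernel_importance(net_p, fx$test, fx$y_test)
  expect_equal(imp_p$importance, imp_full$importance[perm], tolerance = 1e-12)

  expect_error(kernel_importance(build_network(net_config("cnn4")),
                                 fx$test, fx$y_test),
               class = "rfpursuit_unsupported_variant")
})

test_that("the top-importance kernel matches the true RF drive", {
  bank <- gabor_bank(3, 8, 9)
  np <- 16
  hits <- 0
  for (run in 1:10) {
    neuron <- make_synthetic_neuron(bank, 1, 20, seed = 1200 + run)
    train <- gaussian_noise_stimuli(1200, 20, seed = 1300 + run)
    test <- gaussian_noise_stimuli(400, 20, seed = 1400 + run)
    ytr <- simulate_responses(neuron, train, noise = FALSE)
    yte <- simulate_responses(neuron, test, noise = FALSE)
    net <- train_network(build_network(net_config("fixed", front_end = bank,
                                                  seed = run)),
                         train, ytr, max_epochs = 150, patience = 15)
    imp <- kernel_importance(net, test, yte)
    top <- imp$kernel[which.max(imp$importance)]
    # reference: the channel whose own pooled features carry the most
    # information about the true drive (per-channel least-squares readout)
    nn <- build_network(net_config("fixed", front_end = bank, seed = 1))
    fte <- rfpursuit:::net_forward(nn, rfpursuit:::net_im2col(nn, stimulus_matrix(test)),
                                   length(test))$pooled
    refs <- vapply(seq_len(length(bank)), function(j) {
      fj <- fte[, (j - 1) * np + seq_len(np), drop = FALSE]
      cf <- stats::lm.fit(cbind(1, fj), yte)$coefficients
      cf[is.na(cf)] <- 0
      pearson(as.numeric(cbind(1, fj) %*% cf), yte, warn = FALSE)
    }, 0)
    ref <- which.max(refs)
    if (top == ref || top == neuron$source_index) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
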