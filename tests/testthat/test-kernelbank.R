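test_that("gabor banks have the requested layout and zero DC", {
  b <- gabor_bank(3, 8, 9)
  expect_s3_class(b, "kernel_bank")
  expect_equal(length(b), 24)
  expect_true(all(abs(apply(b$kernels, 3, mean)) < 1e-6))
  expect_true(all(abs(apply(b$kernels, 3, function(m) sum(m^2)) - 1) < 1e-6))
  expect_equal(sort(unique(b$info$orientation_deg)), seq(0, 180 - 22.5, by = 22.5))

  b1 <- gabor_bank(1, 1, 9)
  expect_equal(length(b1), 1)
  expect_equal(b1$info$orientation_deg, 0)

  expect_error(gabor_bank(3, 8, 8), class = "rfpursuit_invalid_argument")
  expect_error(gabor_bank(3, 8, 1), class = "rfpursuit_invalid_argument")
})

test_that("oriented gabor kernels are rotations of the 0-degree kernel", {
  b <- gabor_bank(3, 6, 9)
  for (j in 0:2) {
    k0 <- b$kernels[, , j * 6 + 1]
    for (o in 1:5) {
      theta <- o * 30
      rotated <- rfpursuit:::rotate_kernel(k0, theta)
      rotated <- rotated - mean(rotated)
      rotated <- rotated / sqrt(sum(rotated^2))
      rms <- sqrt(mean((rotated - b$kernels[, , j * 6 + o + 1])^2))
      expect_lt(rms, 1e-3)
    }
  }
})

test_that("LOG banks are zero-sum and rotation-invariant center-surrounds", {
  b <- log_bank(3, 9)
  expect_equal(length(b), 3)
  expect_true(all(abs(apply(b$kernels, 3, sum)) < 1e-6))
  for (i in 1:3) {
    k <- b$kernels[, , i]
    # exact invariance under the grid symmetry (90-degree rotation)
    expect_equal(k, t(k[, 9:1]), tolerance = 1e-12)
    # bilinear 45-degree resampling stays close to the original
    r45 <- rfpursuit:::rotate_kernel(k, 45)
    r45 <- r45 / sqrt(sum(r45^2))
    expect_lt(sqrt(mean((r45 - k)^2)), 0.05)
  }
  expect_error(log_bank(3, 4), class = "rfpursuit_invalid_argument")
})

test_that("rotational expansion has kernel-major order and exact counts", {
  b64 <- with_seed_test(11, kernel_bank(lapply(1:64, function(i) {
    matrix(rnorm(81), 9, 9)
  }), name = "r64"))
  d <- rotate_expand(b64, n_steps = 8, step_deg = 45)
  expect_equal(length(d), 512)
  expect_equal(d$info$rotation_index, rep(0:7, times = 64))
  # rotation step 0 is the identity
  expect_equal(d$kernels[, , 1], b64$kernels[, , 1])
  expect_equal(d$kernels[, , 9], b64$kernels[, , 2])

  same <- rotate_expand(b64, n_steps = 1)
  expect_equal(same$kernels, b64$kernels)

  # 90-degree steps are exact grid permutations: 4 rotations recompose
  d4 <- rotate_expand(b64[1], n_steps = 4, step_deg = 90)
  k0 <- b64$kernels[, , 1] / sqrt(sum(b64$kernels[, , 1]^2))
  expect_equal(d4$kernels[, , 3], k0[9:1, 9:1], tolerance = 1e-12)

  expect_error(rotate_expand(gabor_bank(1, 1)[0], 8),
               class = "rfpursuit_invalid_argument")

  # expansion count invariant on random bank sizes
  for (n in c(2, 5)) {
    bn <- b64[seq_len(n)]
    expect_equal(length(rotate_expand(bn, 3, 30)), n * 3)
  }
})

test_that("subset selection filters noise and redundancy deterministically", {
  bank <- fixture_mixed_bank()
  expect_equal(length(bank), 64)
  sel <- select_subset(bank, 24, seed = 7)
  expect_equal(length(sel), 24)
  sel2 <- select_subset(bank, 24, seed = 7)
  expect_identical(sel$info$source_id, sel2$info$source_id)
  expect_false(identical(
    select_subset(bank, 24, seed = 8)$info$source_id,
    sel$info$source_id
  ))

  # pure-noise kernels never survive the high-frequency filter
  expect_false(any(grepl("^k", sel$info$source_id) &
                     sel$info$family == "derived" &
                     tidy(sel)$high_freq_power > 0.5))
  expect_true(all(tidy(sel)$high_freq_power <= 0.5))

  # exhaustive selection keeps all survivors in stable order
  all_surv <- select_subset(bank, n = NULL, seed = 1)
  expect_identical(select_subset(bank, length(all_surv), seed = 3)$info,
                   all_surv$info)

  # idempotence: re-filtering the selection removes nothing
  again <- select_subset(all_surv, n = NULL, seed = 1)
  expect_equal(length(again), length(all_surv))

  expect_error(select_subset(bank, 1000),
               class = "rfpursuit_infeasible_selection")
  expect_match(
    tryCatch(select_subset(bank, 1000), error = conditionMessage),
    "survive"
  )
})

test_that("bank concatenation preserves order and validates sizes", {
  gb <- gabor_bank(3, 8, 9)
  lb <- log_bank(3, 9)
  gl <- concat_banks(gb, lb)
  expect_equal(length(gl), 27)
  expect_equal(gl$kernels[, , 25], lb$kernels[, , 1])
  expect_equal(gl$info$family, c(rep("gabor", 24), rep("log", 3)))

  expect_equal(concat_banks(gb, gb[0])$kernels, gb$kernels)
  expect_error(concat_banks(gb, log_bank(3, 7)),
               class = "rfpursuit_invalid_argument")

  for (na in c(1, 4)) {
    expect_equal(length(concat_banks(gb[seq_len(na)], lb)), na + 3)
  }
})

test_that("aggregated power spectra obey delta/DC/Parseval identities", {
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  bi <- kernel_bank(array(imp, c(9, 9, 1)), normalized = FALSE)
  sp <- aggregate_power_spectrum(bi, 16)
  expect_true(all(abs(sp - sp[1, 1]) < 1e-12))  # flat spectrum

  # without padding, a constant kernel concentrates all energy in DC
  cons <- kernel_bank(array(1, c(9, 9, 1)), normalized = FALSE)
  spc <- aggregate_power_spectrum(cons, 9)
  dc <- spc[5, 5]  # centered DC bin
  expect_gt(dc, 0)
  expect_lt(sum(spc) - dc, sum(spc) * 1e-12)

  gb <- gabor_bank(2, 4, 9)
  spg <- aggregate_power_spectrum(gb, 32)
  expect_true(all(spg >= 0))
  energy <- sum(apply(gb$kernels, 3, function(m) sum(m^2)))
  expect_equal(sum(spg), 32^2 * energy, tolerance = 1e-6)

  expect_error(aggregate_power_spectrum(gb[0], 32),
               class = "rfpursuit_invalid_argument")
  expect_error(aggregate_power_spectrum(gb, 5),
               class = "rfpursuit_invalid_argument")
})

test_that("gabor and sparse-code banks share radial spectral support", {
  gb <- gabor_bank(3, 8, 9)
  csc <- fixture_csc_bank()
  expect_gt(spectral_overlap(gb, csc, 64), 0.5)
})
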