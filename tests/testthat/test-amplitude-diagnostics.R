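test_that("amplitude sets validate shape and enforce pair symmetry", {
  expect_error(amplitude_set(array(0, c(2, 3, 2, 2))),
               class = "noodiag_dimension_error")
  expect_error(amplitude_set(matrix(0, 2, 2)), class = "noodiag_dimension_error")
  expect_error(amplitude_set(array(0, c(0, 0, 2, 2))),
               class = "noodiag_dimension_error")
  bad <- array(0, c(2, 2, 2, 2)); bad[1, 2, 1, 2] <- 1e-3
  expect_warning(t <- amplitude_set(bad), "symmetrizing")
  expect_equal(t$t2, aperm(t$t2, c(2, 1, 4, 3)))
  nf <- array(NaN, c(1, 1, 1, 1))
  expect_error(amplitude_set(nf), class = "noodiag_invalid_amplitudes")
})

test_that("D2 matches its SVD oracles and basic limits", {
  z <- amplitude_set(array(0, c(2, 2, 3, 3)))
  expect_identical(d2_diagnostic(z)$value, 0)

  one <- array(0, c(2, 2, 3, 3)); one[1, 1, 1, 1] <- 0.1
  for (m in c("per-occupied-max", "compound"))
    expect_equal(d2_diagnostic(amplitude_set(one), m)$value, 0.1,
                 tolerance = 1e-14)

  set.seed(21)
  t2 <- array(rnorm(3 * 3 * 4 * 4, sd = 0.05), c(3, 3, 4, 4))
  t2 <- (t2 + aperm(t2, c(2, 1, 4, 3))) / 2
  t <- amplitude_set(t2)
  expect_equal(d2_diagnostic(t, "compound")$value, oracle_d2_compound(t2),
               tolerance = 1e-12)
  expect_equal(d2_diagnostic(t)$value, oracle_d2_per_occ(t2),
               tolerance = 1e-12)
})

test_that("D2 is scale-equivariant and relabeling-invariant", {
  for (seed in 1:5) {
    t1 <- rand_amplitudes(seed, scale = 0.05)
    t2 <- amplitude_set(3 * t1$t2)
    for (m in c("per-occupied-max", "compound")) {
      expect_equal(d2_diagnostic(t2, m)$value, 3 * d2_diagnostic(t1, m)$value,
                   tolerance = 1e-12)
      perm <- amplitude_set(aperm(t1$t2, c(2, 1, 4, 3)))
      expect_equal(d2_diagnostic(perm, m)$value, d2_diagnostic(t1, m)$value,
                   tolerance = 1e-12)
    }
  }
})

test_that("density blocks reproduce the HF limit and the one-amplitude contraction", {
  z <- amplitude_set(array(0, c(3, 3, 2, 2)))
  bz <- mp2_density_blocks(z)
  expect_equal(bz$occ_block, diag(2, 3))
  expect_equal(bz$vir_block, matrix(0, 2, 2))
  expect_equal(approx_density_blocks(z)$occ_block, bz$occ_block)

  tau <- 0.1
  one <- array(0, c(2, 2, 2, 2)); one[1, 1, 1, 1] <- tau
  t <- amplitude_set(one)
  bf <- mp2_density_blocks(t)
  ba <- approx_density_blocks(t)
  # spin-adapted contraction: full correction -2 tau^2 (u = 2t - t gives t),
  # exchange-free correction -4 tau^2; traces balance exactly
  expect_equal(bf$occ_block[1, 1], 2 - 2 * tau^2, tolerance = 1e-14)
  expect_equal(bf$vir_block[1, 1], 2 * tau^2, tolerance = 1e-14)
  expect_equal(ba$occ_block[1, 1], 2 - 4 * tau^2, tolerance = 1e-14)
  expect_equal(ba$vir_block[1, 1], 4 * tau^2, tolerance = 1e-14)
  orc <- oracle_blocks(one, approximate = FALSE)
  orca <- oracle_blocks(one, approximate = TRUE)
  expect_equal(ba$occ_block - bf$occ_block, orca$occ - orc$occ,
               tolerance = 1e-14)  # difference is exactly the omitted term
})

test_that("vectorized contractions equal the index-loop oracle", {
  for (seed in 1:8) {
    t <- rand_amplitudes(seed)
    orc <- oracle_blocks(t$t2, FALSE)
    orca <- oracle_blocks(t$t2, TRUE)
    bf <- mp2_density_blocks(t)
    ba <- approx_density_blocks(t)
    expect_equal(bf$occ_block, orc$occ, tolerance = 1e-12)
    expect_equal(bf$vir_block, orc$vir, tolerance = 1e-12)
    expect_equal(ba$occ_block, orca$occ, tolerance = 1e-12)
    expect_equal(ba$vir_block, orca$vir, tolerance = 1e-12)
    expect_equal(sum(diag(bf$occ_block)) + sum(diag(bf$vir_block)),
                 2 * t$n_occ, tolerance = 1e-12)
  }
})

test_that("extreme occupancies come from the block eigenproblems", {
  z <- mp2_density_blocks(amplitude_set(array(0, c(2, 2, 2, 2))))
  xz <- extreme_occupations(z)
  expect_equal(xz$n_h, 2)
  expect_equal(xz$n_l, 0)

  tau <- 0.1
  one <- array(0, c(2, 2, 2, 2)); one[1, 1, 1, 1] <- tau
  x1 <- extreme_occupations(mp2_density_blocks(amplitude_set(one)))
  expect_equal(x1$n_h, 2 - 2 * tau^2, tolerance = 1e-12)
  expect_equal(x1$n_l, 2 * tau^2, tolerance = 1e-12)

  for (seed in 1:5) {
    t <- rand_amplitudes(seed)
    b <- mp2_density_blocks(t)
    x <- extreme_occupations(b)
    expect_equal(x$n_h, min(eigen(b$occ_block, symmetric = TRUE)$values),
                 tolerance = 1e-12)
    expect_equal(x$n_l, max(eigen(b$vir_block, symmetric = TRUE)$values),
                 tolerance = 1e-12)
  }

  asym <- z; asym$occ_block[1, 2] <- asym$occ_block[1, 2] + 1e-4
  expect_error(extreme_occupations(asym), class = "noodiag_symmetry_error")
})

test_that("exchange-free blocks overestimate correlation, increasingly with amplitude", {
  mean_gap <- vapply(c(0.01, 0.05, 0.1, 0.2), function(scale) {
    gaps <- vapply(1:60, function(seed) {
      t <- rand_amplitudes(seed + 1000, scale = scale)
      xf <- extreme_occupations(mp2_density_blocks(t))
      xa <- extreme_occupations(approx_density_blocks(t))
      expect_lte(xa$n_h, xf$n_h + 1e-10)
      expect_gte(xa$n_l, xf$n_l - 1e-10)
      xf$n_h - xa$n_h
    }, numeric(1))
    mean(gaps)
  }, numeric(1))
  expect_true(all(diff(mean_gap) > 0))
})

test_that("frontier-occupancy formula reproduces nd_max and its bounds", {
  expect_identical(indmax_from_blocks(list(n_h = 2, n_l = 0)), 0)
  expect_identical(indmax_from_blocks(list(n_h = 1, n_l = 1)), 0.125)
  expect_equal(indmax_from_blocks(list(n_h = 1.98, n_l = 0.02)), 0.00495,
               tolerance = 1e-14)
  expect_error(indmax_from_blocks(list(n_h = 2.5, n_l = 0)),
               class = "noodiag_range_error")

  # the extreme eigenvalue dominates second-order spectra, so the pair
  # formula equals nd_max over the full eigen-spectrum
  for (seed in 1:5) {
    t <- rand_amplitudes(seed, scale = 0.1)
    b <- mp2_density_blocks(t)
    expect_equal(indmax_from_blocks(extreme_occupations(b)),
                 nd_max(occupancies_from_blocks(b)), tolerance = 1e-10)
  }
})

test_that("the D2 bridge is zero at zero, monotone, and tracks computed values", {
  expect_identical(predict_indmax_from_d2(0), 0)
  expect_gt(predict_indmax_from_d2(0.18), predict_indmax_from_d2(0.15))
  d <- seq(0, 0.45, by = 0.05)
  expect_true(all(diff(predict_indmax_from_d2(d)) > 0))

  # the analytic map tracks the full-block value across an ensemble
  vals <- vapply(1:30, function(seed) {
    t <- sample_amplitudes(sample(2:4, 1), sample(2:5, 1),
                           stats::runif(1, 0.02, 0.2), seed = seed + 500)
    d2 <- d2_diagnostic(t)$value
    full <- indmax_from_blocks(extreme_occupations(mp2_density_blocks(t)))
    c(predict_indmax_from_d2(d2), full)
  }, numeric(2))
  expect_gte(stats::cor(vals[1, ], vals[2, ], method = "spearman"), 0.9)
})

test_that("amplitude sampler is deterministic, linear in scale, RNG-clean", {
  t1 <- sample_amplitudes(3, 4, 0.05, seed = 11)
  t2 <- sample_amplitudes(3, 4, 0.05, seed = 11)
  expect_identical(t1$t2, t2$t2)
  t3 <- sample_amplitudes(3, 4, 0.10, seed = 11)
  expect_equal(t3$t2, 2 * t1$t2, tolerance = 1e-14)
  expect_identical(d2_diagnostic(t3)$value, 2 * d2_diagnostic(t1)$value)
  expect_identical(sample_amplitudes(2, 2, 0, seed = 1)$t2,
                   array(0, c(2, 2, 2, 2)))

  set.seed(99); before <- .Random.seed
  invisible(sample_amplitudes(2, 3, 0.1, seed = 5))
  expect_identical(.Random.seed, before)  # caller RNG stream untouched

  g <- sample_amplitudes(3, 3, 0.05, seed = 2, structure = "gaussian")
  expect_equal(g$t2, aperm(g$t2, c(2, 1, 4, 3)))
  expect_error(sample_amplitudes(0, 3, 0.1, 1), class = "noodiag_parameter_error")
  expect_error(sample_amplitudes(2, 3, -0.1, 1), class = "noodiag_parameter_error")
})
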