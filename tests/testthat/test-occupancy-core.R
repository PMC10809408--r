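test_that("occupancy containers validate, clip and order their input", {
  s <- spin_occupancy_set(c(0.4, 0.9, 0.7), c(1, 0.6, 0.4), n_alpha = 2, n_beta = 2)
  expect_equal(s$occ_alpha, c(0.9, 0.7, 0.4))  # stored descending
  expect_equal(s$occ_beta, c(1, 0.6, 0.4))

  # mild negatives (relaxed-density artifacts) are clipped with a warning
  expect_warning(s2 <- spin_occupancy_set(c(1, -1e-8), n_alpha = 1),
                 "clipping")
  expect_equal(s2$occ_alpha, c(1, 0))
  # beyond the tolerance: error naming the offending index
  err <- tryCatch(spin_occupancy_set(c(1, -1e-3)), error = identity)
  expect_s3_class(err, "noodiag_invalid_occupancy")
  expect_match(conditionMessage(err), "index 2")

  # trace mismatch is a warning, not an error
  expect_warning(spin_occupancy_set(c(0.5, 0.5), n_alpha = 2), "sum to")

  # closed-shell conversion round-trips exactly
  cs <- closed_shell_occupancies(c(1.9, 0.1))
  sp <- as_spin_occupancy_set(cs)
  expect_identical(sp$occ_alpha, cs$occ / 2)
  expect_identical(sp$occ_beta, cs$occ / 2)
  expect_identical(n_electrons(sp), n_electrons(cs))
  expect_error(closed_shell_occupancies(c(1, 1, 1)),
               class = "noodiag_invalid_occupancy")  # odd electron count
})

test_that("nondynamic index matches limits and the direct-sum oracle", {
  expect_identical(nondynamic_index(spin_occupancy_set(c(1, 1, 0, 0))), 0)
  expect_identical(nondynamic_index(closed_shell_occupancies(c(1, 1))), 0.5)
  set.seed(101)
  n <- rand_channel(4, 20)
  s <- spin_occupancy_set(n, n, n_alpha = 4, n_beta = 4)
  expect_equal(nondynamic_index(s), oracle_ind(c(s$occ_alpha, s$occ_beta)),
               tolerance = 1e-12)
})

test_that("dynamic/total indices satisfy their limits and grow with orbital count", {
  idem <- spin_occupancy_set(c(1, 1, 0), n_alpha = 2)
  expect_equal(dynamic_total_indices(idem), list(i_d = 0, i_t = 0))

  half <- suppressWarnings(spin_occupancy_set(c(1, 0.5, 0), c(1, 0, 0),
                                              n_alpha = 1, n_beta = 1))
  dt <- dynamic_total_indices(half)
  expect_equal(dt$i_t, 0.25, tolerance = 1e-14)
  expect_equal(dt$i_d, 0.125, tolerance = 1e-14)

  i_d_at <- function(M) {
    s <- spin_occupancy_set(rep(1 / M, M), rep(1 / M, M),
                            n_alpha = 1, n_beta = 1)
    dt <- dynamic_total_indices(s)
    expect_equal(dt$i_d + nondynamic_index(s), dt$i_t, tolerance = 1e-12)
    expect_equal(dt$i_d, oracle_it(rep(1 / M, 2 * M)) -
                   oracle_ind(rep(1 / M, 2 * M)), tolerance = 1e-12)
    dt$i_d
  }
  vals <- vapply(c(10, 50, 250), i_d_at, numeric(1))
  expect_true(all(diff(vals) > 0))  # unbounded growth with orbital count
})

test_that("size-intensive indices scale by 2/N and stay in range", {
  expect_equal(size_intensive_indices(closed_shell_occupancies(c(1, 1))),
               list(i_nd_hat = 0.5, i_d_hat = 0.5))
  expect_equal(size_intensive_indices(spin_occupancy_set(c(1, 0)))$i_nd_hat, 0)
  empty <- structure(list(occ_alpha = numeric(0), occ_beta = numeric(0),
                          n_alpha = 0L, n_beta = 0L, label = ""),
                     class = "spin_occupancy_set")
  expect_error(size_intensive_indices(empty), class = "noodiag_zero_electrons")
  # supremum regime: all occupations N/M stay bounded by 1
  for (M in c(10, 50, 250)) {
    s <- spin_occupancy_set(rep(1 / M, M), rep(1 / M, M),
                            n_alpha = 1, n_beta = 1)
    expect_lte(size_intensive_indices(s)$i_nd_hat, 1)
  }
})

test_that("occupied/virtual split reconstructs the intensive index exactly", {
  sp0 <- split_occ_vir(spin_occupancy_set(c(1, 1, 0, 0)))
  expect_equal(sp0, list(i_nd_hat_occ = 0, i_nd_hat_vir = 0))

  sp <- split_occ_vir(closed_shell_occupancies(c(1.9, 0.1)))
  expect_equal(sp$i_nd_hat_occ, 0.0475, tolerance = 1e-14)
  expect_equal(sp$i_nd_hat_vir, 0.0475, tolerance = 1e-14)

  set.seed(7)
  for (k in 1:25) {
    s <- rand_spin_set()
    sp <- split_occ_vir(s)
    expect_equal(sp$i_nd_hat_occ + sp$i_nd_hat_vir,
                 size_intensive_indices(s)$i_nd_hat, tolerance = 1e-12)
  }

  too_few <- structure(list(occ_alpha = 0.5, occ_beta = 0.5,
                            n_alpha = 2L, n_beta = 1L, label = ""),
                       class = "spin_occupancy_set")
  expect_error(split_occ_vir(too_few), class = "noodiag_dimension_error")
  # degenerate boundary occupation warns
  expect_warning(split_occ_vir(spin_occupancy_set(c(0.5, 0.5), n_alpha = 1,
                                                  occ_beta = c(1, 0),
                                                  n_beta = 1)),
                 "degenerate")
})

test_that("particle-hole asymmetry is small for model CISD-like solutions", {
  specs <- list(model_spec("hubbard-dimer", U = 1),
                model_spec("hubbard-dimer", U = 3),
                model_spec("two-level-pairing", U = 0.5),
                model_spec("hubbard-chain", sites = 4, U = 1),
                model_spec("hubbard-chain", sites = 4, U = 2),
                model_spec("hubbard-chain", sites = 6, U = 1))
  for (sp in specs) {
    rep <- correlation_report(exact_diagonalize(sp)$occupancies)
    expect_lte(rep$ph_asymmetry, 0.2)
  }
})

test_that("maximal contribution hits 1/8 exactly at half occupation", {
  expect_identical(nd_max(spin_occupancy_set(c(1, 0))), 0)
  expect_identical(nd_max(suppressWarnings(
    spin_occupancy_set(c(1, 0.5, 0), c(1, 0, 0), n_alpha = 1, n_beta = 1))),
    0.125)
  expect_equal(nd_max(closed_shell_occupancies(c(1.98, 0.02))), 0.00495,
               tolerance = 1e-14)
})

test_that("classification follows the method thresholds and overrides", {
  expect_identical(classify_mr(0.020, "mp2"), "non-MR")
  expect_identical(classify_mr(0.040, "mp2"), "MR")
  expect_identical(classify_mr(0.030, "ccsd"), "caution")
  expect_identical(classify_mr(0.033, "mp2"), "caution")
  # at the lower boundary the non-MR region is open, so caution begins there
  expect_identical(classify_mr(0.030, "MP2"), "caution")
  expect_identical(classify_mr(0.0299, "mp2"), "non-MR")
  expect_identical(classify_mr(0.037, "mp2"), "MR")  # upper boundary inclusive
  err <- tryCatch(classify_mr(0.02, "casscf"), error = identity)
  expect_s3_class(err, "noodiag_missing_threshold")
  expect_match(conditionMessage(err), "user-defined")
  custom <- threshold_table("casscf", 0.01, 0.02)
  expect_identical(classify_mr(0.015, "casscf", custom), "caution")
  expect_error(threshold_table("x", 0.5, 0.4),
               class = "noodiag_invalid_thresholds")
  expect_error(classify_mr(0.5, "mp2"), class = "noodiag_range_error")
})

test_that("correlation report is compositionally consistent", {
  idem <- spin_occupancy_set(c(1, 1, 0, 0))
  r <- correlation_report(idem)
  expect_identical(r$classification, "not-classified")
  expect_true(all(c(r$i_nd, r$i_d, r$i_t, r$i_nd_hat, r$i_nd_max) == 0))

  strong <- closed_shell_occupancies(c(1, 1))
  # the fully entangled pair has a degenerate occupied/virtual boundary
  expect_warning(  # both spin channels sit on the boundary
    expect_warning(correlation_report(strong, method = "ccsd"), "degenerate"),
    "degenerate")
  r2 <- suppressWarnings(correlation_report(strong, method = "ccsd"))
  expect_equal(r2$i_nd_hat, 0.5)
  expect_equal(r2$i_nd_max, 0.125)
  expect_identical(r2$classification, "MR")

  set.seed(42)
  s <- rand_spin_set()
  r3 <- correlation_report(s, method = "mp2")
  expect_identical(r3$i_nd, nondynamic_index(s))
  expect_identical(r3$i_t, dynamic_total_indices(s)$i_t)
  expect_identical(r3$i_nd_hat, size_intensive_indices(s)$i_nd_hat)
  expect_identical(r3$i_nd_max, nd_max(s))
  expect_identical(r3$i_nd_hat_occ + r3$i_nd_hat_vir, r3$i_nd_hat)
  expect_identical(r3$i_nd + r3$i_d, r3$i_t)
  expect_identical(r3$classification, classify_mr(nd_max(s), "mp2"))
})

test_that("indices are invariant under input permutation and spin/spatial form", {
  set.seed(9)
  for (k in 1:10) {
    occ <- rand_channel(2, 7)
    a <- closed_shell_occupancies(2 * occ, n_electrons = 4)
    b <- closed_shell_occupancies(2 * sample(occ), n_electrons = 4)
    s <- spin_occupancy_set(occ, occ, n_alpha = 2, n_beta = 2)
    expect_equal(nondynamic_index(a), nondynamic_index(b), tolerance = 1e-14)
    expect_equal(nondynamic_index(a), nondynamic_index(s), tolerance = 1e-12)
    expect_equal(nd_max(a), nd_max(s), tolerance = 1e-12)
    expect_equal(dynamic_total_indices(a)$i_t, dynamic_total_indices(s)$i_t,
                 tolerance = 1e-12)
  }
})

test_that("total correlation vanishes only on idempotent occupancies", {
  set.seed(13)
  for (k in 1:20) {
    s <- rand_spin_set()
    frac <- any(c(s$occ_alpha, s$occ_beta) %% 1 != 0)
    expect_identical(dynamic_total_indices(s)$i_t > 0, frac)
  }
})

test_that("alternative normalization constants propagate through one knob", {
  const <- index_constants(spin_prefactor = 1)
  s <- closed_shell_occupancies(c(1.5, 0.5))
  expect_equal(nondynamic_index(s, const), 2 * nondynamic_index(s))
})
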