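test_that("contrast primitives satisfy their defining algebra", {
  # quantum catch of the unit integrand over the full range
  g <- canonical_grid()
  one <- spectrum(g, rep(1, 401), "sensitivity")
  oner <- spectrum(g, rep(1, 401), "normalized_reflectance")
  expect_equal(quantum_catch(one, oner, flat_illuminant(g)), 400)
  dark <- flat_illuminant(g, 0)
  expect_equal(quantum_catch(one, oner, dark), 0)

  # Gaussian sensitivity x flat reflectance: 1-nm trapezoid vs 0.01-nm Riemann
  qs <- spectrum(g, exp(-((g - 542) / 40)^2), "sensitivity")
  half <- spectrum(g, rep(0.5, 401), "normalized_reflectance")
  got <- quantum_catch(qs, half, flat_illuminant(g))
  fine <- seq(300, 700, 0.01)
  oracle <- sum(exp(-((fine - 542) / 40)^2) * 0.5) * 0.01
  expect_lt(abs(got / oracle - 1), 1e-3)

  # log-ratio channel contrast
  expect_equal(receptor_contrast(3, 3), 0)
  expect_equal(receptor_contrast(exp(1) * 7, 7), 1)
  set.seed(1)
  qa <- runif(50, 0.1, 10); qb <- runif(50, 0.1, 10)
  expect_equal(receptor_contrast(qa, qb), log(qa) - log(qb),
               tolerance = 1e-12)
  expect_error(receptor_contrast(0, 1), "positive")

  # chromatic contrast closed forms
  expect_equal(chromatic_contrast(c(0, 0, 0)), 0)
  expect_equal(chromatic_contrast(c(1, 0, 0), c(1, 1, 1)), sqrt(2 / 3))
  df <- c(0.3, -0.2, 0.9)
  expect_equal(chromatic_contrast(df + 5, c(0.13, 0.06, 0.12)),
               chromatic_contrast(df, c(0.13, 0.06, 0.12)), tolerance = 1e-12)
  # with equal omegas and two channels identical: |df difference| * sqrt(2/3)
  expect_equal(chromatic_contrast(c(0.4, 0.4, 1.1), c(1, 1, 1)),
               0.7 * sqrt(2 / 3), tolerance = 1e-12)
  expect_error(chromatic_contrast(c(1, 0, 0), c(0, 1, 1)), "positive")

  # Michelson contrast
  expect_equal(michelson_contrast(5, 5), 0)
  expect_equal(michelson_contrast(3, 1), 0.5)
  expect_equal(michelson_contrast(1, 3), 0.5)
  expect_equal(michelson_contrast(3e4, 1e4), 0.5)
  expect_error(michelson_contrast(0, 0), "zero")
})

test_that("delta_S is invariant to intensity scaling while C follows the ratio", {
  set.seed(42)
  rs <- receptor_set()
  for (rep_i in 1:20) {
    rfun <- random_reflectance_fun()
    r <- as_reflectance_spectrum(rfun)
    for (k in c(0.1, 0.7, 5)) {
      scaled <- spectrum(r$wavelength_nm, k * r$value,
                         "normalized_reflectance")
      d <- discriminate_pair(r, scaled, rs)
      expect_lt(d$delta_s, 1e-9)
      expect_equal(d$michelson_c, abs(1 - k) / (1 + k), tolerance = 1e-9)
    }
  }
})

test_that("a 0.7x intensity copy is achromatically but not chromatically distinct", {
  base <- generate_leaf_series(seed = 3)$series[[1]]$mean_spectrum
  dim_leaf <- spectrum(base$wavelength_nm, 0.7 * base$value,
                       "normalized_reflectance")
  d <- discriminate_pair(base, dim_leaf)
  expect_lt(d$delta_s, 1e-6)
  expect_equal(d$michelson_c, 0.3 / 1.7, tolerance = 1e-9)
  expect_false(d$chromatic_call)
  expect_true(d$achromatic_call)
})

test_that("self-comparison gives zero contrasts and negative calls", {
  leaf <- generate_leaf_series(seed = 5)$series[[2]]
  d <- discriminate_pair(leaf, leaf)
  expect_equal(d$delta_s, 0)
  expect_equal(d$michelson_c, 0)
  expect_false(d$chromatic_call)
  expect_false(d$achromatic_call)
})

test_that("pipeline matches the monolithic fine-grid brute force within 0.5%", {
  set.seed(2024)
  rs <- receptor_set()
  for (case in 1:12) {
    rfun_a <- random_reflectance_fun()
    rfun_b <- random_reflectance_fun()
    ora <- oracle_pair(rfun_a, rfun_b, step = 0.1)
    got <- discriminate_pair(as_reflectance_spectrum(rfun_a),
                             as_reflectance_spectrum(rfun_b), rs)
    expect_lt(abs(got$delta_s / ora$delta_s - 1), 0.005)
    expect_lt(abs(got$michelson_c / ora$michelson - 1), 0.005)
    expect_lt(max(abs(got$catches / ora$catches - 1)), 0.005)
  }
})

test_that("discrimination matrices are symmetric with zero diagonals", {
  leaves <- generate_leaf_series(leaf_generator_config(n_leaves = 5),
                                 seed = 9)
  dm <- discrimination_matrix(leaves$series)
  expect_equal(dm$delta_s, t(dm$delta_s))
  expect_equal(dm$michelson_c, t(dm$michelson_c))
  expect_equal(diag(dm$delta_s), rep(0, 5), ignore_attr = TRUE)
  expect_equal(diag(dm$michelson_c), rep(0, 5), ignore_attr = TRUE)

  # identical two-leaf series -> zero matrices
  g <- canonical_grid()
  r <- as_reflectance_spectrum(function(l) 20 + 10 * exp(-((l - 545) / 60)^2))
  dm2 <- discrimination_matrix(list(r, r))
  expect_equal(max(dm2$delta_s), 0)
  expect_equal(max(dm2$michelson_c), 0)
})

test_that("zone classification follows the achromatic threshold", {
  g <- canonical_grid()
  base_fun <- function(l) 20 + 15 * exp(-((l - 545) / 60)^2)
  base <- as_reflectance_spectrum(base_fun)
  # leaves 2-4 nearly identical to leaf 1; 5-7 dimmed strongly
  mk <- function(f) spectrum(g, f * base$value, "normalized_reflectance")
  series <- c(list(base), lapply(c(0.97, 0.96, 0.95), mk),
              lapply(c(0.7, 0.65, 0.6), mk))
  dm <- discrimination_matrix(series)
  zones <- classify_zones(dm)
  expect_equal(unname(zones),
               c("top", "middle", "middle", "middle",
                 "bottom", "bottom", "bottom"))

  # all-identical series: everything middle except the reference
  dm_id <- discrimination_matrix(list(base, base, base))
  expect_equal(unname(classify_zones(dm_id)), c("top", "middle", "middle"))

  # raising the threshold can only move leaves from bottom to middle
  for (c0 in c(0.02, 0.08, 0.2, 0.5)) {
    z_lo <- classify_zones(dm, c_threshold = c0)
    z_hi <- classify_zones(dm, c_threshold = c0 + 0.05)
    moved <- z_lo == "middle" & z_hi == "bottom"
    expect_false(any(moved))
  }
})
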