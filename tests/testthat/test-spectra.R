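test_that("spectrum constructor enforces grid and value invariants", {
  expect_error(spectrum(c(400, 400, 410), c(1, 2, 3)), "ascending")
  expect_error(spectrum(c(290, 400), c(1, 1)), "300")
  expect_warning(s <- spectrum(c(400, 500), c(-1, 2)), "clipped")
  expect_equal(s$value, c(0, 2))
})

test_that("resample is exact on constants, identity grids and linear ramps", {
  const <- spectrum(c(300, 700), c(5, 5), "illuminant")
  expect_equal(resample(const, canonical_grid())$value,
               rep(5, 401))

  s <- spectrum(seq(300, 700, 50), runif(9), "raw")
  expect_equal(resample(s, seq(300, 700, 50))$value, s$value)

  ramp <- spectrum(c(300, 700), c(0, 1), "raw")
  expect_equal(resample(ramp, c(400, 500))$value, c(0.25, 0.5))

  expect_error(resample(spectrum(c(400, 600), c(1, 1)), canonical_grid()),
               "span")
})

test_that("white-standard normalization follows the ratio definition", {
  g <- canonical_grid()
  w <- spectrum(g, runif(401, 10, 20), "white_standard")
  expect_equal(normalize_reflectance(w, w)$value, rep(100, 401))

  zero <- spectrum(g, rep(0, 401), "raw")
  expect_equal(normalize_reflectance(zero, w)$value, rep(0, 401))

  half <- spectrum(g, 0.5 * w$value, "raw")
  expect_equal(normalize_reflectance(half, w)$value, rep(50, 401))

  # joint rescaling of sample and standard cancels
  k <- 3.7
  s <- spectrum(g, runif(401, 1, 9), "raw")
  r1 <- normalize_reflectance(s, w)
  r2 <- normalize_reflectance(spectrum(g, k * s$value, "raw"),
                              spectrum(g, k * w$value, "white_standard"))
  expect_equal(r1$value, r2$value)

  wbad <- w; wbad$value[101] <- 0
  expect_error(normalize_reflectance(s, wbad), "400 nm")
})

test_that("reflectance intensity integrates correctly", {
  g <- canonical_grid()
  expect_equal(reflectance_intensity(
    spectrum(g, rep(100, 401), "normalized_reflectance")), 40000)
  expect_equal(reflectance_intensity(
    spectrum(g, rep(0, 401), "normalized_reflectance")), 0)

  # triangle peaking at 500: trapezoid on the 1-nm grid vs 0.1-nm Riemann
  tri <- function(l) 100 * pmax(1 - abs(l - 500) / 200, 0)
  got <- reflectance_intensity(spectrum(g, tri(g), "normalized_reflectance"))
  fine <- seq(300, 700, 0.1)
  oracle <- sum(tri(fine)) * 0.1
  expect_lt(abs(got / oracle - 1), 1e-3)

  expect_error(reflectance_intensity(
    spectrum(400:700, rep(1, 301), "normalized_reflectance")), "span")
  expect_error(reflectance_intensity(spectrum(g, rep(1, 401), "raw")),
               "normalized")
})

test_that("intensity is linear and agrees with a 10x finer-grid oracle", {
  set.seed(7)
  g <- canonical_grid()
  for (rep_i in 1:5) {
    rfun1 <- random_reflectance_fun()
    rfun2 <- random_reflectance_fun()
    r1 <- as_reflectance_spectrum(rfun1)
    r2 <- as_reflectance_spectrum(rfun2)
    a <- runif(1, 0.2, 2); b <- runif(1, 0.2, 2)
    lin <- spectrum(g, a * r1$value + b * r2$value, "normalized_reflectance")
    expect_equal(reflectance_intensity(lin),
                 a * reflectance_intensity(r1) + b * reflectance_intensity(r2),
                 tolerance = 1e-9)

    fine <- seq(300, 700, 0.1)
    oracle <- pracma::trapz(fine, rfun1(fine))
    expect_lt(abs(reflectance_intensity(r1) / oracle - 1), 0.005)
  }
})

test_that("leaf series averages replicates pointwise on a shared grid", {
  g <- canonical_grid()
  r1 <- spectrum(g, rep(10, 401), "normalized_reflectance")
  r2 <- spectrum(g, rep(30, 401), "normalized_reflectance")
  ls <- leaf_series(2, list(r1, r2))
  expect_equal(ls$mean_spectrum$value, rep(20, 401))
  expect_error(leaf_series(1, list(r1, spectrum(300:699, rep(1, 400)))),
               "grid")
})
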