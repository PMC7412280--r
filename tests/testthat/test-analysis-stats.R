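test_that("pearson_r matches the closed-form covariance formula", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 2.9, 5.1, 6.8, 12.0)
  # hand-computed product-moment formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_hand, tolerance = 1e-10)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(3, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("ols_fit matches the normal equations exactly", {
  x <- c(0, 1, 2, 5, 9, 10)
  rec <- ols_fit(x, 1.2 * x - 10)
  expect_equal(rec$slope, 1.2, tolerance = 1e-10)
  expect_equal(rec$intercept, -10, tolerance = 1e-10)
  expect_equal(rec$pearson_r, 1)
  expect_equal(rec$p_value, 0)

  set.seed(3)
  y <- 0.5 * x + rnorm(6)
  rec2 <- ols_fit(x, y)
  # normal-equation solution
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  expect_equal(rec2$slope, b, tolerance = 1e-10)
  expect_equal(rec2$intercept, a, tolerance = 1e-10)
  expect_error(ols_fit(x, rep(1, 6)), "constant")
})

test_that("hue regression distinguishes intensity scaling from hue change", {
  leaves <- generate_leaf_series(
    leaf_generator_config(noise_sd = 0), seed = 1)
  tab <- hue_regression_table(leaves$series)
  truth <- leaves$truth$affine
  expect_equal(tab$slope, truth$a[-1], tolerance = 1e-9)
  expect_equal(tab$intercept, truth$b[-1], tolerance = 1e-7)
  expect_true(all(tab$pearson_r > 0.999))
  expect_true(all(tab$hue_change))   # nonzero intercepts = hue drift

  # identical spectra: a = 1, b = 0, no hue change
  base <- leaves$series[[1]]
  tab_id <- hue_regression_table(list(base, base, base))
  expect_equal(tab_id$slope, c(1, 1))
  expect_equal(tab_id$intercept, c(0, 0))
  expect_false(any(tab_id$hue_change))

  # pure intensity scaling: b = 0 exactly, flagged as no hue change
  g <- base$mean_spectrum$wavelength_nm
  scaled <- spectrum(g, 1.3 * base$mean_spectrum$value,
                     "normalized_reflectance")
  tab_sc <- hue_regression_table(list(base$mean_spectrum, scaled))
  expect_equal(tab_sc$slope, 1.3, tolerance = 1e-12)
  expect_lt(abs(tab_sc$intercept), 1e-8)
  expect_false(tab_sc$hue_change)
})

test_that("reflected intensity declines linearly with leaf age", {
  leaves <- generate_leaf_series(seed = 1)
  rec <- intensity_age_regression(leaves$series)
  expect_lt(rec$slope, 0)
  expect_gte(abs(rec$pearson_r), 0.8)
  expect_equal(rec$n, 11)

  # exact line and constant-input contracts
  fake <- lapply(1:4, function(i) {
    spectrum(canonical_grid(), rep(50 - 5 * i, 401),
             "normalized_reflectance")
  })
  rec2 <- intensity_age_regression(fake)
  expect_equal(rec2$pearson_r, -1)
  expect_equal(rec2$slope, -5 * 400, tolerance = 1e-9)
})

test_that("trap-count regression recovers deterministic generating constants", {
  hsb <- default_hsb_table()
  counts <- generate_choice_counts(hsb, c(a = 0.411, b = -11.12),
                                   predictor = "S", mode = "deterministic",
                                   seed = 1)
  tab <- trap_count_correlations(counts, hsb[, c("leaf_index", "S")])
  male <- tab[tab$sex == "male", ]
  expect_equal(male$slope, 0.411, tolerance = 1e-9)
  expect_equal(male$intercept, -11.12, tolerance = 1e-9)
  expect_equal(male$pearson_r, 1, tolerance = 1e-12)

  # permuted counts destroy the correlation on average
  set.seed(99)
  rr <- replicate(100, {
    perm <- counts
    for (sx in unique(perm$sex)) for (rp in unique(perm$replicate)) {
      sel <- perm$sex == sx & perm$replicate == rp & perm$choice_index <= 11
      perm$count[sel] <- sample(perm$count[sel])
    }
    tab_p <- trap_count_correlations(perm, hsb[, c("leaf_index", "S")])
    mean(abs(tab_p$pearson_r))
  })
  expect_lt(median(rr), 0.5)

  # constant counts are degenerate
  const <- counts; const$count <- 5
  expect_error(trap_count_correlations(const, hsb[, c("leaf_index", "S")]),
               "constant")
})

test_that("rpkm follows the unit-cancelling arithmetic", {
  expect_equal(rpkm(10, 1e6, 1000), 10)
  expect_equal(rpkm(0, 1e6, 1000), 0)
  expect_error(rpkm(1, 0, 1000), "> 0")
  expect_error(rpkm(1, 1e6, 0), "> 0")
  # linear in reads, inverse-linear in depth and length
  expect_equal(rpkm(20, 1e6, 1000), 2 * rpkm(10, 1e6, 1000))
  expect_equal(rpkm(10, 2e6, 1000), rpkm(10, 1e6, 1000) / 2)
  expect_equal(rpkm(10, 1e6, 2000), rpkm(10, 1e6, 1000) / 2)
  # opsin expression ratio normalized to the blue channel
  vals <- rpkm(c(0.13, 1, 7.73) * 500, 1e6, 1000)
  expect_equal(vals / vals[2], c(0.13, 1, 7.73))
})
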