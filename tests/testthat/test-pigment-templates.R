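# Frozen reference values were computed from the published nomogram formulas
# in an independent numpy script (alpha bands normalized to 1 at lambda_max).

test_that("templates equal 1 at their peak and match reference values", {
  expect_equal(template_value(pigment(542), 542), 1)
  expect_equal(template_value(pigment(356), 356), 1)

  # Govardovskii A1 alpha band
  expect_equal(template_value(pigment(542), 500), 0.7001688517,
               tolerance = 1e-8)
  expect_equal(template_value(pigment(542), 600), 0.3835110260,
               tolerance = 1e-8)
  expect_equal(template_value(pigment(435), 400), 0.6818147908,
               tolerance = 1e-8)
  expect_equal(template_value(pigment(435), 480), 0.3856510519,
               tolerance = 1e-8)

  # Stavenga modified lognormal (UV pigment)
  expect_equal(template_value(pigment(356), 320), 0.5437864436,
               tolerance = 1e-8)
  expect_equal(template_value(pigment(356), 400), 0.2703639045,
               tolerance = 1e-8)

  # long-wavelength tail of the UV pigment is essentially dark
  expect_lt(template_value(pigment(356), 700), 0.01)
})

test_that("family dispatch and domain errors behave as specified", {
  expect_equal(pigment(356)$resolved_family, "stavenga")
  expect_equal(pigment(435)$resolved_family, "govardovskii")
  expect_equal(pigment(542)$resolved_family, "govardovskii")
  expect_equal(pigment(356, family = "govardovskii")$resolved_family,
               "govardovskii")
  expect_error(pigment(290), "300")
  expect_error(pigment(700), "700")
  expect_error(template_value(pigment(500), 250), "300")
})

test_that("beta band adds a secondary UV lobe to green pigments", {
  g <- canonical_grid()
  with_beta <- template_value(pigment(542, beta_band = TRUE), g)
  without <- template_value(pigment(542, beta_band = FALSE), g)
  uv <- g >= 330 & g <= 390
  # secondary lobe present only with the beta band
  expect_gt(max(with_beta[uv]), 0.2)
  expect_lt(max(without[uv]), 0.05)
  # beta band leaves the alpha peak region essentially untouched
  expect_equal(with_beta[g == 542], without[g == 542], tolerance = 1e-3)
})

test_that("templates are finite, non-negative and unimodal in the alpha band",
{
  g <- canonical_grid()
  for (lmax in c(340, 380, 420, 500, 560, 620)) {
    v <- template_value(pigment(lmax, beta_band = FALSE), g)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
    # single interior maximum at lmax
    expect_equal(g[which.max(v)], lmax)
    expect_true(all(diff(v[g <= lmax]) >= -1e-12) ||
                  max(abs(diff(sign(diff(v))))) <= 2)
  }
})

test_that("receptor set validates its invariants", {
  expect_error(receptor_set(c(435, 435, 542)), "increasing")
  expect_error(receptor_set(amplitudes = c(0, 0, 0)), "zero")
  expect_error(receptor_set(weber_fractions = c(0.1, 0, 0.1)), "positive")
})

test_that("composite sensitivity is a normalized weighted template sum", {
  g <- canonical_grid()
  rs1 <- receptor_set(amplitudes = c(0, 0, 1), beta_band = rep(FALSE, 3))
  comp <- composite_sensitivity(rs1, g)
  tmpl <- template_value(pigment(542, beta_band = FALSE), g)
  expect_equal(comp$value, tmpl / tmpl[g == 542], tolerance = 1e-12)

  # invariance to uniform amplitude scaling
  rs_a <- receptor_set(amplitudes = c(1, 0.6, 6.4))
  rs_b <- receptor_set(amplitudes = 2 * c(1, 0.6, 6.4))
  expect_equal(composite_sensitivity(rs_a, g)$value,
               composite_sensitivity(rs_b, g)$value, tolerance = 1e-12)

  # the fitted leafhopper set: primary peak near 542, secondary near 356
  comp <- composite_sensitivity(receptor_set(), g)
  expect_equal(comp$value[g == 542], 1)
  expect_lte(abs(g[which.max(comp$value)] - 542), 2)
  uv <- g <= 400
  uv_peak <- g[uv][which.max(comp$value[uv])]
  expect_lte(abs(uv_peak - 356), 6)
  # and the secondary peak is a genuine local maximum
  expect_gt(max(comp$value[uv]), comp$value[g == 410])
})
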