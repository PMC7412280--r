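# Independent brute-force oracle for the discrimination pipeline.
#
# Everything here is written as one monolithic computation on a fine
# wavelength grid, re-deriving the nomogram templates and contrast formulas
# from the published equations without calling any package internals, so it
# can serve as a genuinely independent cross-check.

oracle_template <- function(lambda, lmax, beta = FALSE) {
  if (lmax < 400) {
    x <- log10(lambda / lmax)
    v <- exp(-380 * x^2 * (1 + 6.09 * x + (3 * 6.09^2 / 8) * x^2))
    if (beta) {
      xb <- log10(lambda / 340)
      v <- v + 0.29 * exp(-247 * xb^2 * (1 + 3.59 * xb + (3 * 3.59^2 / 8) * xb^2))
    }
  } else {
    xx <- lmax / lambda
    aa <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
    raw <- function(x) 1 / (exp(69.7 * (aa - x)) + exp(28 * (0.922 - x)) +
                              exp(-14.9 * (1.104 - x)) + 0.674)
    v <- raw(xx) / raw(1)
    if (beta) {
      lmb <- 189 + 0.315 * lmax
      bw <- -40.5 + 0.195 * lmax
      v <- v + 0.26 * exp(-((lambda - lmb) / bw)^2)
    }
  }
  pmax(v, 0)
}

# Riemann-sum quantum catch of channel (lmax, beta) viewing reflectance
# function rfun under illuminant function ifun, on a fine grid.
oracle_catch <- function(rfun, lmax, beta, ifun = function(l) 1,
                         step = 0.1) {
  l <- seq(300, 700, by = step)
  sum(oracle_template(l, lmax, beta) * rfun(l) * ifun(l)) * step
}

# Full brute-force pairwise comparison: returns delta_S and Michelson C
# (L-channel convention) for two reflectance functions.
oracle_pair <- function(rfun_a, rfun_b,
                        lmax = c(356, 435, 542),
                        beta = c(FALSE, FALSE, TRUE),
                        weber = c(0.13, 0.06, 0.12),
                        step = 0.1) {
  qa <- vapply(1:3, function(j) oracle_catch(rfun_a, lmax[j], beta[j],
                                             step = step), 0)
  qb <- vapply(1:3, function(j) oracle_catch(rfun_b, lmax[j], beta[j],
                                             step = step), 0)
  f <- log(qa / qb)
  num <- weber[1]^2 * (f[3] - f[2])^2 + weber[2]^2 * (f[3] - f[1])^2 +
    weber[3]^2 * (f[2] - f[1])^2
  den <- (weber[1] * weber[2])^2 + (weber[1] * weber[3])^2 +
    (weber[2] * weber[3])^2
  list(delta_s = sqrt(num / den),
       michelson = abs(qa[3] - qb[3]) / (qa[3] + qb[3]),
       catches = rbind(a = qa, b = qb))
}

# Random smooth reflectance "measurement": a positive Gaussian mixture,
# returned as an analytic function so both the package path (1-nm trapezoid)
# and the oracle (0.1-nm Riemann) can evaluate it exactly.
random_reflectance_fun <- function() {
  k <- sample(2:4, 1)
  mu <- runif(k, 350, 650)
  sd_ <- runif(k, 30, 90)
  amp <- runif(k, 5, 30)
  base <- runif(1, 5, 25)
  function(l) {
    v <- rep(base, length(l))
    for (j in seq_len(k)) v <- v + amp[j] * exp(-((l - mu[j]) / sd_[j])^2)
    v
  }
}

as_reflectance_spectrum <- function(rfun, grid = 300:700) {
  spectrum(grid, rfun(grid), "normalized_reflectance")
}
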