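test_that("Sneddon cone force matches the closed form and is quadratic", {
  # 10 kPa, 35 deg, nu 0.5, 500 nm: (2/pi)(E/(1-nu^2))tan(theta) delta^2
  expect_equal(sneddonForce(500, E = 10, theta = 35, nu = 0.5),
               1.48588654528, tolerance = 1e-10)
  expect_identical(sneddonForce(0, 10), 0)
  d <- c(50, 200, 700)
  expect_equal(sneddonForce(2 * d, 3), 4 * sneddonForce(d, 3))
  expect_error(sneddonForce(-1, 10), "non-negative")
})

test_that("BECC reduces to Sneddon for vanishing delta/h and stiffens thin films", {
  for (E in c(0.1, 1, 10)) {
    d <- 1e-6 * 5000
    rel <- (beccForce(d, E, 35, 0.5, h = 5000) - sneddonForce(d, E)) /
      sneddonForce(d, E)
    expect_lt(abs(rel), 1e-5)
  }
  # monotone: at fixed delta and E the force decreases with thickness
  hs <- c(1500, 2000, 4000, 8000)
  f <- vapply(hs, function(h) beccForce(600, 10, 35, 0.5, h), 0)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > sneddonForce(600, 10)))
  expect_error(beccForce(100, 10, 35, 0.5, h = -1), "positive")
  expect_error(beccForce(2100, 10, 35, 0.5, h = 2000), "exceeds thickness")
})

test_that("BECC fixture value is reproduced", {
  # independent arithmetic with the transcribed coefficients:
  # B(w) = 1 + (2*1.7795/pi^2) w + (16*1.7795^2) w^2, w = delta tan(theta)/h
  tt <- tan(35 * pi / 180)
  w <- 500 * tt / 2000
  S <- (2 / pi) * (10e-6 / 0.75) * tt * 500^2
  oracle <- S * (1 + (2 * 1.7795 / pi^2) * w + (16 * 1.7795^2) * w^2)
  expect_equal(beccForce(500, 10, 35, 0.5, h = 2000), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 3.88661591396, tolerance = 1e-10)  # frozen regression
})

test_that("modulus fits recover noiseless data exactly", {
  delta <- seq(0, 800, by = 4)
  fS <- fitModulus(delta, sneddonForce(delta, 10), "sneddon")
  expect_equal(youngsModulus(fS), 10, tolerance = 1e-9)
  expect_equal(rSquared(fS), 1, tolerance = 1e-12)
  expect_true(isConverged(fS))

  db <- seq(0, 900, by = 4)
  fB <- fitModulus(db, beccForce(db, 10, 35, 0.5, h = 2000), "becc", h = 2000)
  expect_equal(youngsModulus(fB), 10, tolerance = 1e-9)

  # optimiser cross-check on the same data (independent route)
  g <- function(E) sum((sneddonForce(delta, E) - sneddonForce(delta, 10))^2)
  opt <- optimize(g, c(1, 100))$minimum
  expect_equal(youngsModulus(fS), opt, tolerance = 1e-4)
})

test_that("modulus fit is scale equivariant and flags degenerate input", {
  delta <- seq(0, 500, by = 5)
  f <- sneddonForce(delta, 4)
  E1 <- youngsModulus(fitModulus(delta, f, "sneddon"))
  E3 <- youngsModulus(fitModulus(delta, 3 * f, "sneddon"))
  expect_equal(E3, 3 * E1, tolerance = 1e-10)
  expect_error(fitModulus(delta, numeric(length(delta)), "sneddon"),
               "degenerate")
  expect_error(fitModulus(delta[1:3], f[1:3], "sneddon"), "insufficient|fewer")
  expect_error(fitModulus(delta, f, "becc"), "thickness")
})

test_that("ignoring the bottom effect inflates the apparent modulus", {
  delta <- seq(0, 1000, by = 5)
  fThin <- beccForce(delta, 10, 35, 0.5, h = 2000)
  fit <- fitModulus(delta, fThin, "sneddon")
  expect_gt(youngsModulus(fit), 10)
})

test_that("power-law fits recover exponents exactly on clean power laws", {
  delta <- seq(1, 500, length.out = 120)
  for (x in c(1, 2, 3, 4)) {
    fit <- fitPowerLaw(delta, 2e-6 * delta^x)
    expect_equal(powerLawExponent(fit), x, tolerance = 1e-6)
    expect_equal(fit@A, 2e-6, tolerance = 1e-4)
  }
  # thin-film data over a deep window push the local exponent above 2
  dd <- seq(400, 1400, by = 5)
  fit <- fitPowerLaw(dd, beccForce(dd, 10, 35, 0.5, h = 2000))
  expect_gt(powerLawExponent(fit), 2)
  expect_error(fitPowerLaw(delta, -2e-6 * delta^2), "insufficient|fewer")
})

test_that("power-law fit agrees with an established NLS optimiser", {
  skip_if_not_installed("minpack.lm")
  set.seed(42)
  delta <- seq(5, 400, length.out = 90)
  force <- 3e-6 * delta^2.4
  force <- force + rnorm(length(force), 0, 0.02 * max(force))
  keep <- force > 0
  fit <- fitPowerLaw(delta[keep], force[keep])
  ref <- minpack.lm::nlsLM(
    f ~ A * d^x, data = data.frame(d = delta[keep], f = force[keep]),
    start = list(A = 1e-6, x = 2))
  expect_equal(powerLawExponent(fit), coef(ref)[["x"]], tolerance = 1e-4)
  expect_equal(fit@A, coef(ref)[["A"]], tolerance = 1e-3)
})

test_that("modulus recovery under 1% force noise is within 2% (median)", {
  delta <- seq(0, 800, length.out = 200)
  f0 <- sneddonForce(delta, 10)
  set.seed(7)
  err <- replicate(200, {
    f <- f0 + rnorm(length(f0), 0, 0.01 * max(f0))
    abs(youngsModulus(fitModulus(delta, f, "sneddon")) - 10) / 10
  })
  expect_lt(median(err), 0.02)
})
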