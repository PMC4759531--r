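test_that("candidate margins reflect each component's stencil", {
  # 1 nm sampling so window arithmetic is transparent
  Z <- seq(0, 1000, by = 1)
  set.seed(1)
  fc <- forceCurve(Z, rnorm(length(Z), 0, 0.5), k = 0.03, Zglass = 900)
  apex <- length(Z)

  rov <- candidateRange(fc, strategySpec("rov", searchRange = "full"))
  expect_identical(min(rov$candidates), 51L)
  expect_identical(max(rov$candidates), apex - 50L)

  de <- candidateRange(fc, strategySpec("delta_e", searchRange = "full"))
  expect_identical(min(de$candidates), 4L)          # 3-candidate stencil edge
  expect_identical(max(de$candidates), apex - 9L - 3L)

  gof <- candidateRange(fc, strategySpec("gof_whole", searchRange = "full"))
  expect_identical(max(gof$candidates), apex - 9L)

  both <- candidateRange(fc, strategySpec(c("gof_whole", "rov", "delta_e"),
                                          searchRange = "full"))
  expect_identical(min(both$candidates),
                   max(min(rov$candidates), min(de$candidates)))
  expect_identical(max(both$candidates),
                   min(max(rov$candidates), max(de$candidates), apex - 9L))

  expect_error(candidateRange(fc, strategySpec("rov", rovWindow = 2,
                                               searchRange = "full")),
               ">= 5")
})

test_that("goodness-of-fit traces are bounded by 1 and localise clean contact", {
  sim <- generateCurve(smallProfile(noiseSd = 0), seed = 11)
  cand <- candidateRange(sim$curve, strategySpec("gof_whole"))$candidates
  for (mode in c("whole", "low")) {
    tr <- testparamGoF(sim$curve, cand, mode = mode, model = "becc")
    expect_true(all(tr[is.finite(tr)] <= 1 + 1e-12))
    expect_lte(abs(cand[which.max(tr)] - sim$truth$cpIndex), 2L)
  }
})

test_that("low mode fits exactly the prescribed fraction of contact points", {
  sim <- generateCurve(smallProfile(noiseSd = 0), seed = 2)
  curve <- sim$curve
  apex <- which.max(piezoZ(curve))
  i <- sim$truth$cpIndex
  tr <- testparamGoF(curve, i, mode = "low", model = "becc", fraction = 1 / 3)
  # reproduce the same fit by hand on the first third of contact points
  nc <- apex - i + 1L
  nLow <- max(10L, ceiling(nc / 3))
  j <- i:(i + nLow - 1L)
  delta <- (piezoZ(curve)[j] - piezoZ(curve)[i]) -
    (deflection(curve)[j] - deflection(curve)[i])
  force <- springConstant(curve) * (deflection(curve)[j] - deflection(curve)[i])
  h <- glassPosition(curve) - piezoZ(curve)[i]
  manual <- fitModulus(delta, force, "becc", h = h)
  expect_equal(as.numeric(tr), rSquared(manual), tolerance = 1e-12)
  expect_equal(attr(tr, "E"), youngsModulus(manual), tolerance = 1e-12)
})

test_that("log-modulus derivative trace matches analytic series", {
  expect_error(testparamDeltaE(rep(NA_real_, 20)), "consecutive")
  # constant modulus -> zero derivative everywhere valid
  tr0 <- testparamDeltaE(rep(5, 20))
  expect_true(all(abs(tr0[4:17]) < 1e-12))
  expect_true(all(is.na(tr0[c(1:3, 18:20)])))
  # exponential decay: the 6th-order stencil is exact for linear ln E
  c0 <- 0.07
  trE <- testparamDeltaE(exp(-c0 * seq_len(30)))
  expect_equal(trE[4:27], rep(c0, 24), tolerance = 1e-10)
  # scale invariance of the log derivative
  E <- exp(sin(seq(0, 3, length.out = 25)))
  expect_equal(testparamDeltaE(E), testparamDeltaE(17 * E), tolerance = 1e-9)
  # invalid entries poison only the stencils that touch them
  E2 <- rep(2, 20); E2[10] <- NA
  tr2 <- testparamDeltaE(E2)
  expect_true(all(is.na(tr2[7:13])))
  expect_false(anyNA(tr2[c(4:6, 14:17)]))
})

test_that("RoV is near 1 off-contact and peaks close to a clean contact", {
  # pooled pure-noise traces: expect the F-ratio mean, well inside [0.8, 1.25]
  vals <- unlist(lapply(1:8, function(s) {
    fc <- noiseCurve(n = 2048L, seed = s)  # 50 nm window = 20 samples
    cand <- candidateRange(fc, strategySpec("rov", searchRange = "full"))$candidates
    as.numeric(testparamRoV(fc, cand))
  }))
  expect_gt(mean(vals, na.rm = TRUE), 0.8)
  expect_lt(mean(vals, na.rm = TRUE), 1.25)

  # noiseless flat denominator hits the variance floor without failing
  sim0 <- generateCurve(smallProfile(noiseSd = 0), seed = 3)
  cand0 <- candidateRange(sim0$curve, strategySpec("rov"))$candidates
  tr0 <- testparamRoV(sim0$curve, cand0)
  expect_true(any(attr(tr0, "floored")))
  expect_true(any(is.finite(tr0)))

  # with low noise the peak sits within a window-width of the true CP
  errs <- vapply(1:12, function(s) {
    sim <- generateCurve(sampleProfile(noiseSd = 0.1), seed = 100 + s)
    cand <- candidateRange(sim$curve, strategySpec("rov"))$candidates
    tr <- testparamRoV(sim$curve, cand)
    dz <- diff(piezoZ(sim$curve)[1:2])
    (cand[which.max(tr)] - sim$truth$cpIndex) * dz
  }, 0)
  expect_lt(median(abs(errs)), 150)  # nm; bounded by the 50-nm window geometry
})

test_that("power-law exponent trace peaks at a clean contact point", {
  sim <- generateCurve(sampleProfile(noiseSd = 0, nPoints = 1024L), seed = 4)
  cand <- candidateRange(sim$curve, strategySpec("ple"))$candidates
  tr <- testparamPLE(sim$curve, cand)
  expect_lte(abs(cand[which.max(tr)] - sim$truth$cpIndex), 2L)
  # exponents well inside the contact region drift away from 2
  deep <- which(cand > sim$truth$cpIndex + 40L)
  expect_gt(median(abs(attr(tr, "x")[deep] - 2), na.rm = TRUE), 0.2)
})

test_that("trace normalisation maps onto [0,1] preserving the argmax", {
  expect_equal(normalizeTrace(c(1, 3, 2)), c(0, 1, 0.5))
  set.seed(5)
  tr <- rnorm(50); tr[c(3, 20)] <- NA
  nt <- normalizeTrace(tr)
  expect_identical(which.max(nt), which.max(tr))
  expect_identical(is.na(nt), is.na(tr))
  expect_equal(range(nt, na.rm = TRUE), c(0, 1))
  expect_warning(normalizeTrace(rep(2, 10)), class = "noPeakWarning")
  expect_error(normalizeTrace(c(1, NA, NA)), "fewer than 2")
})

test_that("trace combination multiplies, propagates NA and keeps the grid", {
  a <- c(0.2, 1, 0.5, NA)
  expect_equal(combineTraces(list(a)), a)
  expect_equal(combineTraces(list(a, a)), a^2)
  expect_identical(which.max(combineTraces(list(a, a))), which.max(a))
  b <- c(1, 0.1, 0.6, 0.9)
  expect_equal(combineTraces(list(a, b)), a * b)
  # disjoint unit peaks: the product selects the best joint value
  p1 <- c(1, 0.6, 0.1); p2 <- c(0.1, 0.59, 1)
  expect_identical(which.max(combineTraces(list(p1, p2))), 2L)
  expect_error(combineTraces(list(a, b[1:3])), "grid")
  expect_error(combineTraces(list(c(NA, 1), c(1, NA))),
               class = "combinationError")
})

test_that("detection is deterministic and translation equivariant", {
  sim <- generateCurve(smallProfile(), seed = 21)
  spec <- strategySpec()
  r1 <- findContactPoint(sim$curve, spec)
  r2 <- findContactPoint(sim$curve, spec)
  expect_identical(r1@combined, r2@combined)
  expect_identical(cpIndex(r1), cpIndex(r2))

  shift <- 1234.5
  shifted <- forceCurve(piezoZ(sim$curve) + shift, deflection(sim$curve),
                        k = springConstant(sim$curve),
                        theta = halfAngle(sim$curve),
                        Zglass = glassPosition(sim$curve) + shift)
  rs <- findContactPoint(shifted, spec)
  expect_identical(cpIndex(rs), cpIndex(r1))
  expect_equal(rs@Zcp, r1@Zcp + shift)
})

test_that("every candidate is evaluated and strides subsample the grid", {
  sim <- generateCurve(smallProfile(), seed = 8)
  cp <- findContactPoint(sim$curve, strategySpec())
  expect_length(combinedTrace(cp), length(cp@candidates))
  expect_true(cpIndex(cp) %in% cp@candidates)
  cp3 <- findContactPoint(sim$curve, strategySpec(step = 3L))
  expect_true(all(diff(cp3@candidates) == 3L))
})

test_that("fit-based strategies localise a clean contact point", {
  sim <- generateCurve(smallProfile(noiseSd = 0), seed = 13)
  for (comp in c("gof_whole", "gof_low")) {
    cp <- findContactPoint(sim$curve, strategySpec(comp))
    expect_lte(abs(cpIndex(cp) - sim$truth$cpIndex), 2L)
    expect_false(isLowConfidence(cp))
  }
})

test_that("a contact-free curve never yields a silent index", {
  fc <- noiseCurve(seed = 99)
  # default pre-search finds no contact evidence
  expect_error(findContactPoint(fc, strategySpec()),
               class = "cpDetectionError")
  # full-range search must flag the result instead
  res <- tryCatch(
    findContactPoint(fc, strategySpec(c("gof_low", "rov"),
                                      gofModel = "sneddon",
                                      searchRange = "full")),
    error = function(e) e)
  if (is(res, "CPResult")) expect_true(isLowConfidence(res))
  else expect_s3_class(res, "cpDetectionError")
})

test_that("trace dumps are written with raw, normalised and combined columns", {
  sim <- generateCurve(smallProfile(), seed = 30)
  cp <- findContactPoint(sim$curve, strategySpec())
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraces(cp, path)
  df <- read.delim(path)
  expect_identical(nrow(df), length(cp@candidates))
  expect_true(all(c("gof_low_raw", "rov_norm", "combined") %in% names(df)))
})
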