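test_that("write/read round trip is lossless in both dialects", {
  sim <- generateCurve(smallProfile(), seed = 3)
  fc <- sim$curve
  for (dialect in c("tsv", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeForceCurve(fc, path, dialect = dialect)
    back <- readForceCurve(path, dialect = dialect)
    expect_identical(piezoZ(back), piezoZ(fc))
    expect_identical(deflection(back), deflection(fc))
    expect_identical(springConstant(back), springConstant(fc))
    expect_identical(halfAngle(back), halfAngle(fc))
    expect_identical(poissonRatio(back), poissonRatio(fc))
    expect_identical(glassPosition(back), glassPosition(fc))
    expect_identical(curveLabel(back), curveLabel(fc))
  }
})

test_that("reader names the offending column, line or metadata key", {
  one <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# k: 0.03", "# theta: 35", "Z", "1", "2"), one)
  expect_error(readForceCurve(one), "missing column 'd'")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# k: 0.03", "# theta: 35", "Z\td",
               paste(1:20, 0, sep = "\t"), "21\toops"), bad)
  expect_error(readForceCurve(bad), "parse error at data line 22")

  nometa <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Z\td", paste(1:20, 0, sep = "\t")), nometa)
  expect_error(readForceCurve(nometa), "metadata error.*'k'")
  # the missing key can be supplied as an argument instead
  fc <- readForceCurve(nometa, k = 0.05, theta = 20)
  expect_equal(springConstant(fc), 0.05)
})

test_that("decreasing-Z approaches are flipped to the internal frame", {
  Z <- seq(5000, 0, length.out = 64)     # approach towards smaller Z
  fc <- forceCurve(Z, numeric(64), k = 0.03, Zglass = -200)
  expect_true(fc@flipped)
  expect_true(all(diff(piezoZ(fc)) > 0))
  expect_equal(glassPosition(fc), 200)
  up <- forceCurve(rev(Z), numeric(64), k = 0.03)
  expect_false(up@flipped)
})

test_that("approach/withdraw split partitions indices at the apex", {
  n <- 41L
  Z <- c(seq(0, 5000, length.out = n), seq(4875, 0, length.out = n - 1L))
  fc <- forceCurve(Z, numeric(length(Z)), k = 0.03)
  seg <- splitApproachWithdraw(fc)
  expect_identical(seg$approach@indices, 1:41)
  expect_identical(seg$withdraw@indices, 42:81)
  expect_identical(sort(c(seg$approach@indices, seg$withdraw@indices)),
                   seq_along(Z))

  mono <- forceCurve(seq(0, 5000, length.out = 32), numeric(32), k = 0.03)
  seg2 <- splitApproachWithdraw(mono)
  expect_length(seg2$withdraw@indices, 0L)

  # tie at the apex resolves to the earliest index
  Zt <- c(seq(0, 5000, length.out = 32), 5000, 4000)
  fct <- forceCurve(Zt, numeric(34), k = 0.03)
  expect_identical(max(splitApproachWithdraw(fct)$approach@indices), 32L)

  short <- forceCurve(c(seq(0, 10, length.out = 10),
                        seq(9, 1, length.out = 10)),
                      numeric(20), k = 0.03)
  expect_error(splitApproachWithdraw(short), "degenerate")
})

test_that("force conversion and indentation satisfy their identities", {
  expect_equal(deflectionToForce(0, 0.03), 0)
  expect_equal(deflectionToForce(100, 0.03), 3)
  d <- runif(10)
  expect_equal(deflectionToForce(2 * d, 0.03), 2 * deflectionToForce(d, 0.03))
  expect_error(deflectionToForce(1, -1), "positive")

  n <- 64L
  Z <- seq(0, 1000, length.out = n)
  # rigid substrate: deflection tracks travel exactly -> delta == 0
  rigid <- forceCurve(Z, Z, k = 0.03)
  expect_equal(indentation(rigid, 10L), numeric(n - 9L))
  # free travel: no deflection change -> delta == Z - Zcp
  free <- forceCurve(Z, numeric(n), k = 0.03)
  expect_equal(indentation(free, 10L), Z[10:n] - Z[10L])
  # definition: zero at the contact point itself
  sim <- generateCurve(smallProfile(), seed = 5)
  cpI <- sim$truth$cpIndex
  delta <- indentation(sim$curve, cpI)
  expect_identical(delta[1L], 0)
  expect_error(indentation(sim$curve, 10^6), "approach segment")
})

test_that("indentation is bounded by tip travel while deflection rises", {
  sim <- generateCurve(smallProfile(noiseSd = 0), seed = 9)
  cpI <- sim$truth$cpIndex
  delta <- indentation(sim$curve, cpI)
  travel <- piezoZ(sim$curve)[cpI:which.max(piezoZ(sim$curve))] -
    piezoZ(sim$curve)[cpI]
  expect_true(all(delta >= 0))
  expect_true(all(delta <= travel + 1e-9))
})

test_that("sample height is the distance to the glass reference", {
  expect_equal(sampleHeight(2000, 5000), 3000)
  expect_equal(sampleHeight(5000, 5000), 0)
  off <- 1234.5
  expect_equal(sampleHeight(2000 + off, 5000 + off), sampleHeight(2000, 5000))
  expect_error(sampleHeight(2000, NA), "height unavailable")
})
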