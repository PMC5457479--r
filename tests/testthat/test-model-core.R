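test_that("default parameter set carries the wild-type GV-arrest values", {
  p <- meioParams()
  expect_length(unclass(p), 21)
  expect_identical(p[["ksCycB"]], 0.015)
  expect_identical(p[["kd1CycB"]], 0.015)
  expect_identical(p[["kd2CycB"]], 0.075)
  expect_identical(p[["Cdh1T"]], 1)
  expect_identical(p[["Wee1T"]], 1)
  expect_identical(p[["VaWee"]], 0.375)
  expect_identical(p[["Vi25"]], 0.375)
  expect_identical(p[["ViCdh1"]], 6)
  expect_identical(p[["Jwee"]], 0.01)
})

test_that("parameter construction validates names and signs", {
  expect_error(meioParams(Chd1T = 0.05), "Chd1T")
  expect_error(meioParams(ksCycB = -1), "negative")
  expect_error(meioParams(Cdh1T = 0), "strictly positive")
  expect_error(meioParams(JCdh1 = NaN), "non-finite")
})

test_that("scenario edits copy, never mutate", {
  p <- meioParams()
  p2 <- applyGvbdTrigger(p)
  expect_identical(p[["VaWee"]], 0.375)
  expect_identical(p2[["VaWee"]], 0.075)
  p3 <- applyKnockout(p, "cdh1")
  expect_identical(p[["Cdh1T"]], 1)
  expect_identical(p3[["Cdh1T"]], 0.05)
})

test_that("bundled config file reproduces the wild-type set exactly", {
  path <- system.file("extdata", "wt_params.conf", package = "meioswitch")
  expect_true(nzchar(path))
  p <- readParams(path)
  expect_identical(unclass(p), unclass(meioParams()))
})

test_that("parameter sets round-trip through the key-value format", {
  p <- meioParams(Cdh1T = 0.05, ksc25 = 0.0003)
  tmp <- tempfile(fileext = ".conf")
  writeParams(p, tmp)
  expect_identical(unclass(readParams(tmp)), unclass(p))
  unlink(tmp)
})

test_that("conserved complements are exact subtractions", {
  p <- meioParams()
  gv <- printedGvState()
  cmp <- complements(gv, p)
  expect_identical(cmp[["Cdk1p"]], 0.1701 - 0.04000)
  expect_identical(cmp[["Cdh1p"]], 1 - 0.9759)

  full <- gv; full[["Cdh1"]] <- 1
  expect_identical(complements(full, p)[["Cdh1p"]], 0)
  off <- gv; off[["Wee1"]] <- 0
  expect_identical(complements(off, p)[["Wee1p"]], 1)
})

test_that("negative complements are rejected by name", {
  p <- meioParams()
  bad <- printedGvState(); bad[["Cdk1"]] <- 0.2
  expect_error(complements(bad, p), "Cdk1 > CycBT")
})

test_that("the printed GV-arrest state is (numerically) at rest", {
  d <- modelDerivatives(printedGvState(), meioParams())
  expect_lt(max(abs(d)), 1e-3)
})

test_that("cyclin synthesis-degradation balance closes with Cdh1 = 0", {
  s <- c(CycBT = 1, Cdk1 = 0.5, Cdh1 = 0, Cdc25T = 0.2, Cdc25p = 0.1,
         Wee1 = 0.5)
  d <- modelDerivatives(s, meioParams())
  # ksCycB = kd1CycB = 0.015: synthesis balances basal degradation exactly
  expect_identical(d[["CycBT"]], 0)
})

test_that("the right-hand side matches a hand-expanded transcription", {
  p <- meioParams()
  s0 <- c(CycBT = 0.3, Cdk1 = 0, Cdh1 = 0.5, Cdc25T = 0.1, Cdc25p = 0,
          Wee1 = 0.8)
  d <- modelDerivatives(s0, p)
  # with Cdk1 = 0 and Cdc25p = 0 the activation flux is Va1CDK*Cdc25*Cdk1p
  expect_equal(d[["Cdk1"]],
               p[["ksCycB"]] + p[["Va1CDK"]] * 0.1 * 0.3, tolerance = 1e-14)
  expect_equal(d, rhsByHand(s0, p), tolerance = 1e-14)

  set.seed(42)
  for (i in 1:25) {
    s <- randomState(p)
    expect_equal(modelDerivatives(s, p), rhsByHand(s, p), tolerance = 1e-12)
  }
  pk <- applyGvbdTrigger(applyKnockout(p, "cdh1"))
  set.seed(43)
  for (i in 1:10) {
    s <- randomState(pk)
    expect_equal(modelDerivatives(s, pk), rhsByHand(s, pk),
                 tolerance = 1e-12)
  }
})

test_that("non-finite state components are rejected by name", {
  s <- printedGvState(); s[["Wee1"]] <- NaN
  expect_error(modelDerivatives(s, meioParams()), "Wee1")
})

test_that("complements stay consistent with totals across an Euler step", {
  p <- meioParams()
  set.seed(7)
  for (i in 1:10) {
    s <- randomState(p)
    h <- 1e-3
    s2 <- s + h * modelDerivatives(s, p)
    cmp <- complements(s2, p, check = FALSE)
    expect_equal(cmp[["Cdk1p"]] + s2[["Cdk1"]], s2[["CycBT"]],
                 tolerance = 1e-14)
    expect_equal(cmp[["Cdc25"]] + s2[["Cdc25p"]], s2[["Cdc25T"]],
                 tolerance = 1e-14)
    expect_equal(cmp[["Wee1p"]] + s2[["Wee1"]], p[["Wee1T"]],
                 tolerance = 1e-14)
  }
})

test_that("Goldbeter-Koshland closed form handles the limit cases", {
  expect_equal(goldbeterKoshland(1, 1, 0.15, 0.15), 0.5, tolerance = 1e-14)
  expect_equal(goldbeterKoshland(0, 2, 0.1, 0.1), 0)
  expect_equal(goldbeterKoshland(2, 0, 0.1, 0.1), 1)
  expect_error(goldbeterKoshland(0, 0, 0.1, 0.1), "degenerate")
  expect_error(goldbeterKoshland(1, 1, 0, 0.1), "positive")
})

test_that("Goldbeter-Koshland matches the Cdh1 balance at the GV point", {
  # ViCdh1 * Cdk1 = 6 * 0.04 = 0.24 at GV arrest
  oracle <- gkBisect(1.5, 0.24, 0.15, 0.15)
  expect_equal(goldbeterKoshland(1.5, 0.24, 0.15, 0.15), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.9758, tolerance = 1e-4)
})

test_that("closed form agrees with bisection over a log-spaced grid", {
  grid <- 10^seq(-3, 3, length.out = 13)
  for (J in c(0.01, 0.15, 1)) {
    for (va in grid) {
      for (vi in grid) {
        expect_lt(abs(goldbeterKoshland(va, vi, J, J) -
                        gkBisect(va, vi, J, J)), 1e-10)
      }
    }
  }
})
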