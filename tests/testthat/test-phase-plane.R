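test_that("the pseudo-steady-state lift reproduces the printed totals", {
  p <- meioParams()
  st <- liftState(0.04, 0.9759, p)
  # CycBT = ksCycB/(kd1CycB + kd2CycB*cdh1) at the printed GV Cdh1
  expect_equal(st[["CycBT"]], 0.015 / (0.015 + 0.075 * 0.9759),
               tolerance = 1e-12)
  # printed values carry 4 significant figures (half-ulp ~3e-4 relative)
  expect_equal(st[["CycBT"]], 0.1701, tolerance = 3e-4)
  expect_equal(st[["Cdc25T"]], 0.09295, tolerance = 3e-4)
  # lifted fast variables satisfy their own balances exactly
  d <- modelDerivatives(st, p)
  for (nm in c("CycBT", "Cdc25T", "Cdc25p", "Wee1"))
    expect_lt(abs(d[[nm]]), 1e-10)
})

test_that("lift limit cases and the out-of-region flag behave", {
  p <- meioParams()
  st <- liftState(0, 0.5, p)
  expect_equal(st[["Wee1"]], p[["Wee1T"]], tolerance = 1e-12)
  expect_equal(st[["Cdc25p"]], 0)
  expect_null(attr(liftState(0.04, 0.9759, p), "outOfRegion"))
  # cdk1 beyond the lifted cyclin total leaves the admissible region
  expect_true(isTRUE(attr(liftState(1.1, 0.9759, p), "outOfRegion")))
  expect_error(liftState(-0.1, 0.5, p), "nonnegative")
})

test_that("the Cdh1 nullcline is the decreasing Goldbeter-Koshland curve", {
  p <- meioParams()
  nc <- cdh1Nullcline(p)
  expect_identical(nc$which, "cdh1_balance")
  expect_equal(unname(nc$points[1, "Cdh1"]), p[["Cdh1T"]], tolerance = 1e-12)
  expect_true(all(diff(nc$points[, "Cdh1"]) <= 0))
  # grid point at Cdk1 = 0.04 agrees with the bisection oracle
  at04 <- unname(cdh1Nullcline(p, cdk1Grid = c(0, 0.04))$points[2, "Cdh1"])
  expect_equal(at04, gkBisect(1.5, 6 * 0.04, 0.15, 0.15), tolerance = 1e-10)
  expect_equal(at04, 0.976, tolerance = 1e-3)
  # pointwise evaluation: refinement leaves shared points untouched
  coarse <- cdh1Nullcline(p, cdk1Grid = seq(0, 1, by = 0.1))
  fine <- cdh1Nullcline(p, cdk1Grid = seq(0, 1, by = 0.05))
  expect_equal(coarse$points[, "Cdh1"], fine$points[seq(1, 21, 2), "Cdh1"],
               tolerance = 1e-14)
})

test_that("the Cdk1 nullcline is S-shaped under GV-arrest parameters", {
  p <- meioParams()
  nc <- cdk1Nullcline(p)
  counts <- table(nc$points[, "Cdh1"])
  expect_true(any(counts == 3))     # bistable window exists
  expect_true(all(counts <= 3))
  # every point, lifted, zeroes the Cdk1 balance
  idx <- seq(1, nrow(nc$points), length.out = 25)
  for (i in round(idx)) {
    st <- liftState(nc$points[i, "Cdk1"], nc$points[i, "Cdh1"], p)
    expect_lt(abs(modelDerivatives(st, p)[["Cdk1"]]), 1e-8)
  }
})

test_that("nullcline points satisfy all State invariants or are flagged", {
  p <- meioParams()
  nc <- cdk1Nullcline(p, cdh1Grid = seq(0, 1, length.out = 41))
  for (i in seq_len(nrow(nc$points))) {
    st <- liftState(nc$points[i, "Cdk1"], nc$points[i, "Cdh1"], p)
    if (!isTRUE(attr(st, "outOfRegion")))
      expect_silent(validateState(st, p))
  }
})

test_that("reduced intersections coincide with full-system steady states", {
  sets <- list(
    wild_type_gv = scenarioParams("wild_type_gv"),
    wild_type_gvbd = scenarioParams("wild_type_gvbd"),
    cdh1_ko = scenarioParams("cdh1_ko"),
    cdc25b_ko = scenarioParams("cdc25b_ko")
  )
  for (nm in names(sets)) {
    p <- sets[[nm]]
    xs <- nullclineIntersections(cdk1Nullcline(p), cdh1Nullcline(p), p)
    ss <- findSteadyStates(p)
    full <- t(vapply(ss, function(s) s$state[c("Cdk1", "Cdh1")], numeric(2)))
    expect_identical(nrow(xs), nrow(full))
    expect_lt(max(abs(xs - full)), 1e-6)
  }
})

test_that("the triggered phase plane has a single crossing", {
  p <- applyGvbdTrigger(meioParams())
  xs <- nullclineIntersections(cdk1Nullcline(p), cdh1Nullcline(p), p)
  expect_identical(nrow(xs), 1L)
  expect_lt(xs[1, "Cdh1"], 0.1)
  expect_gt(xs[1, "Cdk1"], 0.5)
})

test_that("non-overlapping curves yield no intersections", {
  p <- meioParams()
  # two synthetic parallel polylines well apart in the plane
  n1 <- structure(list(
    which = "cdk1_balance",
    points = cbind(Cdk1 = seq(0, 0.2, by = 0.05), Cdh1 = 0.1),
    branch = rep(1L, 5)), class = "meio_nullcline")
  n2 <- structure(list(
    which = "cdh1_balance",
    points = cbind(Cdk1 = seq(0.6, 0.8, by = 0.05), Cdh1 = 0.9),
    branch = rep(1L, 5)), class = "meio_nullcline")
  xs <- nullclineIntersections(n1, n2, p)
  expect_identical(nrow(xs), 0L)
})
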