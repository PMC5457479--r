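# Shared triggered wild-type trajectory for the assay tests.
wtTrajectory <- local({
  p <- meioParams()
  simulateModel(applyGvbdTrigger(p), arrestState(p), horizon = 240,
                outputStep = 1, triggerTime = 0)
})

test_that("noiseless sampling reads the trajectory exactly", {
  obs <- sampleKinaseAssay(wtTrajectory, sampleTimes = c(-30, 0, 20, 40))
  expect_identical(obs$time_min, c(-30, 0, 20, 40))
  idx <- match(c(0, 0, 20, 40), wtTrajectory$times)
  expect_equal(obs$readout, unname(wtTrajectory$states[idx, "Cdk1"]),
               tolerance = 1e-12)
  # pre-trigger sample equals the arrested t = 0 value
  expect_identical(obs$readout[1], obs$readout[2])
  # gain scales linearly
  obs2 <- sampleKinaseAssay(wtTrajectory, sampleTimes = c(0, 20), scale = 3)
  expect_equal(obs2$readout, 3 * obs$readout[2:3], tolerance = 1e-12)
})

test_that("sampling is reproducible under a seed and leaves the RNG alone", {
  a <- sampleKinaseAssay(wtTrajectory, noiseSd = 0.1, seed = 11)
  b <- sampleKinaseAssay(wtTrajectory, noiseSd = 0.1, seed = 11)
  expect_identical(a$readout, b$readout)
  c_ <- sampleKinaseAssay(wtTrajectory, noiseSd = 0.1, seed = 12)
  expect_false(identical(a$readout, c_$readout))
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sampleKinaseAssay(wtTrajectory, noiseSd = 0.1,
                                            seed = 5))
  expect_identical(runif(1), before)
})

test_that("the multiplicative noise model is unbiased (law of large numbers)", {
  mu <- approx(wtTrajectory$times, wtTrajectory$states[, "Cdk1"],
               xout = 40)$y
  means <- vapply(1:1000, function(s)
    sampleKinaseAssay(wtTrajectory, sampleTimes = 40, noiseSd = 0.05,
                      seed = s)$readout, numeric(1))
  expect_lt(abs(mean(means) - mu) / mu, 0.01)
})

test_that("degenerate sampling inputs are rejected or clipped", {
  expect_error(sampleKinaseAssay(wtTrajectory, sampleTimes = 500),
               "beyond the trajectory span")
  expect_error(sampleKinaseAssay(wtTrajectory, noiseSd = -1), "nonnegative")
  expect_error(sampleKinaseAssay(wtTrajectory, noiseSd = 0.1), "seed")
  # huge noise occasionally drives readouts negative: clipped with warning
  expect_warning(
    obs <- sampleKinaseAssay(wtTrajectory, sampleTimes = rep(0, 50),
                             noiseSd = 3, seed = 1),
    "clipped")
  expect_true(all(obs$readout >= 0))
})

test_that("observations round-trip through CSV", {
  obs <- sampleKinaseAssay(wtTrajectory, noiseSd = 0.05, seed = 7)
  tmp <- tempfile(fileext = ".csv")
  writeObservations(obs, tmp)
  back <- readObservations(tmp)
  expect_equal(back$readout, obs$readout, tolerance = 1e-12)
  expect_identical(attr(back, "noiseSd"), 0.05)
  unlink(tmp)
})

test_that("a noiseless sparse assay already pins down total Cdh1", {
  obs <- sampleKinaseAssay(wtTrajectory, sampleTimes = c(-30, 0, 20, 40))
  fit <- fitParameters(obs, free = "Cdh1T", nStarts = 2, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["Cdh1T"]] - 1), 0.01)
  # the loss never rises above the best starting value
  expect_lte(fit$loss, fit$initialLoss)
  # estimates respect the declared bounds
  expect_gte(fit$estimates[["Cdh1T"]], 0.01)
})

test_that("fits reject non-identifiable or oversized parameter requests", {
  obs <- sampleKinaseAssay(wtTrajectory, sampleTimes = c(0, 20, 40))
  expect_error(fitParameters(obs, free = "Jwee"), "must be among")
  expect_error(fitParameters(obs, free = c("Cdh1T", "kd2CycB", "ksc25")),
               "out of scope")
  expect_error(fitParameters(obs, free = "Cdh1T", lower = -1), "bounds")
})

test_that("recovery error shrinks with the noise level and with density", {
  sparse <- c(-30, 0, 20, 40)
  seeds <- 1:7
  err <- function(times, noise) {
    median(vapply(seeds, function(s) {
      obs <- sampleKinaseAssay(wtTrajectory, sampleTimes = times,
                               noiseSd = noise,
                               seed = if (noise > 0) s else NULL)
      fit <- fitParameters(obs, free = "Cdh1T", nStarts = 2, seed = s)
      abs(fit$estimates[["Cdh1T"]] - 1)
    }, numeric(1)))
  }
  e <- c(err(sparse, 0.2), err(sparse, 0.1), err(sparse, 0.05),
         err(sparse, 0))
  expect_true(all(diff(e) < 0))
  # the four-point design is weaker than a dense 5-minute grid
  dense <- seq(0, 240, by = 5)
  expect_gt(err(sparse, 0.1), err(dense, 0.1))
})
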