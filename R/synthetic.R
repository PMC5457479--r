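#' Sample a synthetic H1 kinase assay from a trajectory
#'
#' Emulates the sparse radiometric histone-H1 kinase readout of Cdk1
#' activity: a handful of samples around meiotic resumption. Model time 0
#' is the trigger; negative sample times denote the arrested pre-trigger
#' phase, where Cdk1 is stationary, and read the t = 0 value. The default
#' schedule mirrors the assay's GV, GVBD, +20 and +40 min samples.
#'
#' Readouts are `scale * Cdk1(t) * (1 + eps)` with `eps ~ N(0, noiseSd)`
#' independent per sample (multiplicative, gel-densitometry-style noise);
#' `noiseModel = "additive"` uses `scale * Cdk1(t) + N(0, noiseSd * scale)`
#' instead. Negative draws are clipped to 0 with a warning. All randomness
#' comes from `seed`; the caller's RNG state is left untouched.
#'
#' @param trajectory a `meio_trajectory` starting at the trigger (t = 0).
#' @param sampleTimes minutes relative to the trigger; default
#'   `c(-30, 0, 20, 40)`.
#' @param scale gain relating model Cdk1 to readout units (default 1).
#' @param noiseSd relative noise standard deviation (default 0).
#' @param seed integer seed (required when `noiseSd > 0`).
#' @param noiseModel `"multiplicative"` (default) or `"additive"`.
#' @return a `meio_observations`: data.frame with columns `time_min`,
#'   `readout`, plus attributes `scale`, `noiseSd`, `seed`, `noiseModel`.
#' @examples
#' \donttest{
#' tr <- runScenario("wild_type_gvbd")$trajectory
#' sampleKinaseAssay(tr, noiseSd = 0.05, seed = 1)
#' }
#' @export
sampleKinaseAssay <- function(trajectory, sampleTimes = c(-30, 0, 20, 40),
                              scale = 1, noiseSd = 0, seed = NULL,
                              noiseModel = c("multiplicative", "additive")) {
  noiseModel <- match.arg(noiseModel)
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  tmax <- trajectory$times[length(trajectory$times)]
  if (any(sampleTimes > tmax))
    stop("sample time(s) beyond the trajectory span: ",
         paste(sampleTimes[sampleTimes > tmax], collapse = ", "))
  cdk1 <- trajAt(trajectory, "Cdk1", pmax(sampleTimes, 0))
  mu <- scale * cdk1
  if (noiseSd > 0) {
    if (is.null(seed)) stop("a seed is required when noiseSd > 0")
    eps <- withSeed(seed, stats::rnorm(length(mu), 0, noiseSd))
    readout <- if (noiseModel == "multiplicative") mu * (1 + eps)
      else mu + scale * eps
  } else {
    readout <- mu
  }
  if (any(readout < 0)) {
    warning("negative readout(s) clipped to 0")
    readout <- pmax(readout, 0)
  }
  structure(
    data.frame(time_min = sampleTimes, readout = readout),
    scale = scale, noiseSd = noiseSd,
    seed = if (is.null(seed)) NA_integer_ else seed,
    noiseModel = noiseModel,
    class = c("meio_observations", "data.frame"))
}

## Evaluate an expression under a seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read kinase observations as CSV
#'
#' Columns `time_min`, `readout`, `scale`, `noise_sd`, `seed`.
#'
#' @param observations a `meio_observations` object.
#' @param path file path.
#' @return `path` (write) or a `meio_observations` (read).
#' @export
writeObservations <- function(observations, path) {
  df <- data.frame(time_min = observations$time_min,
                   readout = observations$readout,
                   scale = attr(observations, "scale"),
                   noise_sd = attr(observations, "noiseSd"),
                   seed = attr(observations, "seed"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeObservations
#' @export
readObservations <- function(path) {
  df <- utils::read.csv(path)
  structure(data.frame(time_min = df$time_min, readout = df$readout),
            scale = df$scale[1], noiseSd = df$noise_sd[1],
            seed = df$seed[1], noiseModel = "multiplicative",
            class = c("meio_observations", "data.frame"))
}

## Identifiable single-parameter fit targets (chosen by a sensitivity
## screen on the triggered Cdk1 time course; see the methods vignette).
FITTABLE_PARAMS <- c("Cdh1T", "kd2CycB", "ViCdh1", "ksc25")

## Simulated readout means for a candidate parameter override: the
## scenario map shared by generator and fitter — untriggered arrest, then
## the triggered run, Cdk1 read at the sample times.
simulatedReadout <- function(overrides, sampleTimes, scale = 1,
                             rtol = 1e-8, atol = 1e-10) {
  base <- do.call(meioParams, as.list(overrides))
  init <- arrestState(base)
  triggered <- applyGvbdTrigger(base)
  tt <- sort(unique(c(0, pmax(sampleTimes, 0))))
  rhs <- function(t, y, p) list(rhsCore(y, p))
  sol <- deSolve::ode(y = unname(init[STATE_NAMES]), times = tt, func = rhs,
                      parms = unname(unclass(triggered)[PARAM_NAMES]),
                      method = "lsoda", rtol = rtol, atol = atol)
  cdk1 <- stats::approx(sol[, 1], sol[, 3], xout = pmax(sampleTimes, 0))$y
  scale * cdk1
}

#' Fit model parameters to kinase observations
#'
#' Least-squares recovery of one or two free parameters from a (synthetic)
#' Cdk1 kinase time course. Every other parameter is held at its wild-type
#' value; candidate trajectories are generated exactly like the synthetic
#' data (pre-trigger arrest of the candidate set, then the triggered run).
#' The objective (residual sum of squares between simulated and observed
#' readouts) is minimised over log-parameters by `L-BFGS-B`, multi-started
#' from log-uniform draws within the bounds; the best start wins.
#'
#' @param observations a `meio_observations` object.
#' @param free character vector of free parameter names, a subset of
#'   `c("Cdh1T", "kd2CycB", "ViCdh1", "ksc25")` (the identifiable
#'   single-parameter targets), length 1 or 2.
#' @param lower,upper named (or positionally matched) positive bounds for
#'   the free parameters. Defaults: a factor of 100 around wild type.
#' @param nStarts number of optimizer starts (default 6).
#' @param seed integer seed for the start draws (default 1).
#' @return a `meio_fit`: list with `estimates` (named), `loss` (final
#'   residual sum of squares), `initialLoss`, `nStarts`, `converged`.
#' @export
fitParameters <- function(observations, free, lower = NULL, upper = NULL,
                          nStarts = 6, seed = 1) {
  if (!all(free %in% FITTABLE_PARAMS))
    stop("free parameters must be among: ",
         paste(FITTABLE_PARAMS, collapse = ", "))
  if (length(free) > 2)
    stop("joint fits of more than 2 parameters are out of scope")
  wt <- unclass(meioParams())[free]
  if (is.null(lower)) lower <- wt / 100
  if (is.null(upper)) upper <- wt * 100
  lower <- rep_len(as.numeric(lower), length(free))
  upper <- rep_len(as.numeric(upper), length(free))
  if (any(lower <= 0) || any(upper <= lower))
    stop("bounds must satisfy 0 < lower < upper")
  scale <- attr(observations, "scale")
  if (is.null(scale)) scale <- 1
  times <- observations$time_min
  obs <- observations$readout

  objective <- function(logTheta) {
    theta <- stats::setNames(10^logTheta, free)
    sim <- tryCatch(simulatedReadout(theta, times, scale),
                    error = function(e) NULL)
    if (is.null(sim) || any(!is.finite(sim))) return(1e6)
    sum((sim - obs)^2)
  }

  starts <- withSeed(seed, matrix(
    stats::runif(nStarts * length(free), log10(lower), log10(upper)),
    nrow = nStarts, byrow = TRUE))
  best <- NULL
  initialLoss <- Inf
  anyConverged <- FALSE
  for (i in seq_len(nStarts)) {
    f0 <- objective(starts[i, ])
    initialLoss <- min(initialLoss, f0)
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = log10(lower), upper = log10(upper),
                   control = list(maxit = 50, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) anyConverged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(estimates = stats::setNames(rep(NA_real_,
             length(free)), free), loss = NA_real_,
             initialLoss = initialLoss, nStarts = nStarts,
             converged = FALSE), class = "meio_fit"))
  structure(list(
    estimates = stats::setNames(10^best$par, free),
    loss = min(best$value, initialLoss),
    initialLoss = initialLoss,
    nStarts = nStarts,
    converged = anyConverged
  ), class = "meio_fit")
}

#' @export
print.meio_fit <- function(x, ...) {
  cat("Parameter fit (", x$nStarts, " starts, converged = ",
      x$converged, "):\n", sep = "")
  print(x$estimates)
  cat("  residual sum of squares:", format(x$loss), "\n")
  invisible(x)
}
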