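#' Pre-trigger arrest state for a parameter set
#'
#' The resting state a scenario starts from: the stable steady state with
#' highest Cdh1 of the *untriggered* parameter set. For the wild type this
#' is the printed GV-arrest state; knockouts get their own arrest state
#' (the wild-type inits would violate `Cdh1 <= Cdh1T` when total Cdh1 is
#' knocked down). Solved by Newton from a high-Cdh1, low-Cdk1 lifted seed,
#' with a fall-back scan over lifted seeds and, last, a long relaxation
#' integration.
#'
#' @param params an *untriggered* `meio_params` parameter set.
#' @return a named state vector at equilibrium (residual norm < 1e-9).
#' @export
arrestState <- function(params) {
  validateParams(params)
  cdh1T <- params[["Cdh1T"]]
  seeds <- rbind(
    c(0.04, 0.98 * cdh1T),
    c(0.01, 0.95 * cdh1T),
    c(0.10, 0.90 * cdh1T)
  )
  for (i in seq_len(nrow(seeds))) {
    st <- liftState(seeds[i, 1], seeds[i, 2], params)
    st[["Cdk1"]] <- min(st[["Cdk1"]], st[["CycBT"]])
    x <- fullNewton(st, params)
    if (!is.null(x) && admissibleRoot(x, params) && isStableState(x, params))
      return(stats::setNames(x, STATE_NAMES))
  }
  ## relaxation fall-back: integrate the untriggered system to rest
  init <- liftState(0.02, 0.9 * cdh1T, params)
  init[["Cdk1"]] <- min(init[["Cdk1"]], init[["CycBT"]])
  tr <- simulateModel(params, init, horizon = 3000, outputStep = 100)
  x <- fullNewton(tr$states[nrow(tr$states), ], params)
  if (is.null(x)) stop("no arrest steady state found for this parameter set")
  stats::setNames(x, STATE_NAMES)
}

isStableState <- function(state, params) {
  eig <- eigen(modelJacobian(state, params), only.values = TRUE)$values
  all(Re(eig) < -1e-8)
}

#' Run a named scenario
#'
#' Composes the scenario's parameter overrides ([scenarioParams()]), its
#' pre-trigger arrest initial state ([arrestState()]) and the stiff
#' integration ([simulateModel()]), then computes summary metrics on the
#' sampled trajectory (linear interpolation between samples):
#' \describe{
#'   \item{commitmentTime}{first time Cdh1 falls below `0.5 * Cdh1T`
#'     (minutes; `NA` if never) — the model's operational marker of
#'     irreversible commitment to prometaphase.}
#'   \item{cdk1RiseTime}{time from 10% to 90% of the final Cdk1 value
#'     (minutes; `NA` if the trajectory never spans that window).}
#'   \item{peakCdk1}{maximum Cdk1 over the horizon.}
#'   \item{finalState}{state at the horizon.}
#' }
#' Both event thresholds are package definitions (configurable), chosen as
#' monotone, threshold-robust summaries of the simulated time courses.
#'
#' @param name scenario name (see [scenarioParams()]) or a `meio_params`
#'   object for a custom scenario (used as-is, starting from its own
#'   arrest state of the matching untriggered set is not attempted:
#'   supply `initial`).
#' @param horizon,outputStep passed to [simulateModel()].
#' @param initial optional explicit initial state (default: the arrest
#'   state of the untriggered scenario parameter set).
#' @param commitmentFraction Cdh1 commitment threshold as a fraction of
#'   `Cdh1T` (default 0.5).
#' @param riseFractions lower and upper fractions of final Cdk1 for the
#'   rise-time window (default `c(0.1, 0.9)`).
#' @return a `meio_scenario`: list with `name`, `params`, `trajectory`,
#'   `metrics`.
#' @examples
#' \donttest{
#' res <- runScenario("wild_type_gvbd")
#' res$metrics$commitmentTime
#' }
#' @export
runScenario <- function(name, horizon = 480, outputStep = 1, initial = NULL,
                        commitmentFraction = 0.5,
                        riseFractions = c(0.1, 0.9)) {
  if (inherits(name, "meio_params")) {
    params <- name
    name <- "custom"
    if (is.null(initial))
      stop("custom scenarios require an explicit initial state")
  } else {
    name <- match.arg(name, SCENARIO_NAMES)
    params <- scenarioParams(name)
    if (is.null(initial))
      initial <- arrestState(scenarioParams(name, triggered = FALSE))
  }
  triggerTime <- if (identical(name, "wild_type_gv")) NA_real_ else 0
  traj <- simulateModel(params, initial, horizon, outputStep,
                        triggerTime = triggerTime)
  metrics <- trajectoryMetrics(traj, commitmentFraction, riseFractions)
  structure(list(name = name, params = params, trajectory = traj,
                 metrics = metrics),
            class = "meio_scenario")
}

#' @export
print.meio_scenario <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Scenario '%s' (%g min):\n", x$name,
              x$trajectory$times[length(x$trajectory$times)]))
  cat(sprintf("  commitment (Cdh1 < %g*Cdh1T): %s min\n",
              m$commitmentFraction,
              if (is.na(m$commitmentTime)) "not reached"
              else format(round(m$commitmentTime, 2))))
  cat(sprintf("  Cdk1 10-90%% rise time: %s min; peak Cdk1 = %.4f\n",
              if (is.na(m$cdk1RiseTime)) "undefined"
              else format(round(m$cdk1RiseTime, 2)), m$peakCdk1))
  invisible(x)
}

## Summary metrics on a sampled trajectory (linear interpolation).
trajectoryMetrics <- function(traj, commitmentFraction = 0.5,
                              riseFractions = c(0.1, 0.9)) {
  cdh1T <- traj$params[["Cdh1T"]]
  cdh1 <- traj$states[, "Cdh1"]
  cdk1 <- traj$states[, "Cdk1"]
  times <- traj$times
  commitmentTime <- crossingTime(times, cdh1, commitmentFraction * cdh1T,
                                 direction = "down")
  finalCdk1 <- cdk1[length(cdk1)]
  t10 <- crossingTime(times, cdk1, riseFractions[1] * finalCdk1, "up")
  t90 <- crossingTime(times, cdk1, riseFractions[2] * finalCdk1, "up")
  rise <- if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10
  list(commitmentTime = commitmentTime, cdk1RiseTime = rise,
       peakCdk1 = max(cdk1), finalState = traj$states[nrow(traj$states), ],
       commitmentFraction = commitmentFraction,
       riseFractions = riseFractions)
}

## First time y crosses the threshold in the given direction, linearly
## interpolated; NA if never. Starting already past the threshold counts
## as t = times[1].
crossingTime <- function(times, y, threshold, direction = c("down", "up")) {
  direction <- match.arg(direction)
  past <- if (direction == "down") y < threshold else y > threshold
  if (past[1]) return(times[1])
  i <- which(past)[1]
  if (is.na(i)) return(NA_real_)
  t0 <- times[i - 1]; t1 <- times[i]
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(t1)
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Compare scenario results
#'
#' Tabulates the summary metrics of two or more scenario runs on a common
#' horizon. The model is deterministic, so the comparison is a plain
#' ordered table, no statistics.
#'
#' @param results list of `meio_scenario` objects.
#' @return a data.frame with one row per scenario: name, commitment time,
#'   Cdk1 rise time, peak and final Cdk1, final Cdh1.
#' @export
compareScenarios <- function(results) {
  if (length(results) < 2)
    stop("need at least two scenario results to compare")
  horizons <- vapply(results, function(r)
    r$trajectory$times[length(r$trajectory$times)], numeric(1))
  if (max(horizons) - min(horizons) > 1e-9)
    stop("scenario horizons differ; re-run on a common horizon")
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      scenario = r$name,
      commitmentTime = r$metrics$commitmentTime,
      cdk1RiseTime = r$metrics$cdk1RiseTime,
      peakCdk1 = r$metrics$peakCdk1,
      finalCdk1 = r$metrics$finalState[["Cdk1"]],
      finalCdh1 = r$metrics$finalState[["Cdh1"]]
    )
  }))
}
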