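#' Integrate the model through time
#'
#' Adaptive stiff integration (via [deSolve::ode()], `lsoda`) of the
#' six-variable system, with dense output sampled on a regular grid.
#' Components pushed marginally outside their bounds by round-off are
#' clipped back to the bound; violations beyond `clipTol` abort with the
#' last accepted time and state in the error message.
#'
#' @param params a `meio_params` parameter set.
#' @param initial named state vector (see [validateState()]).
#' @param horizon integration horizon in minutes (> 0, or 0 for the
#'   degenerate one-point trajectory). Default 480.
#' @param outputStep output sampling step in minutes (reporting only; the
#'   integrator chooses its own internal steps). Default 1.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param triggerTime bookkeeping only: time (minutes) at which the GVBD
#'   parameter switch was applied to `params`, or `NA` for none.
#' @return a `meio_trajectory`: list with `times` (minutes), `states`
#'   (matrix, one row per time, columns in state order), `params`,
#'   `triggerTime`.
#' @examples
#' tr <- simulateModel(meioParams(), gvArrestState(), horizon = 10)
#' tail(as.data.frame(tr), 2)
#' @export
simulateModel <- function(params, initial, horizon = 480, outputStep = 1,
                          rtol = 1e-8, atol = 1e-10, triggerTime = NA_real_) {
  validateParams(params)
  validateState(initial, params)
  if (!is.finite(horizon) || horizon < 0) stop("horizon must be >= 0")
  if (horizon == 0) {
    states <- matrix(initial[STATE_NAMES], nrow = 1,
                     dimnames = list(NULL, STATE_NAMES))
    return(newTrajectory(0, states, params, triggerTime))
  }
  if (!is.finite(outputStep) || outputStep <= 0)
    stop("outputStep must be > 0")
  times <- seq(0, horizon, by = outputStep)
  if (times[length(times)] < horizon) times <- c(times, horizon)

  pvec <- unname(unclass(params)[PARAM_NAMES])
  rhs <- function(t, y, p) list(rhsCore(y, p))
  sol <- deSolve::ode(y = unname(initial[STATE_NAMES]), times = times,
                      func = rhs, parms = pvec, method = "lsoda",
                      rtol = rtol, atol = atol)
  attr <- attributes(sol)
  if (!is.null(attr$istate) && attr$istate[1] < 0) {
    k <- nrow(sol)
    stop(sprintf(
      "integration failed at t = %.6g; last accepted state: %s",
      sol[k, 1], paste(sprintf("%.6g", sol[k, -1]), collapse = ", ")))
  }
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- STATE_NAMES
  states <- clipStates(states, params)
  newTrajectory(sol[, 1], states, params, triggerTime)
}

## Clip round-off bound violations; abort if a violation exceeds clipTol.
clipStates <- function(states, params, clipTol = 1e-6) {
  lo <- matrix(0, nrow(states), 6)
  hi <- cbind(Inf, states[, "CycBT"], params[["Cdh1T"]], Inf,
              states[, "Cdc25T"], params[["Wee1T"]])
  viol <- pmax(lo - states, states - hi, 0)
  worst <- max(viol)
  if (worst > clipTol) {
    idx <- which(viol == worst, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "state bound violated beyond tolerance (%.3g) for %s at row %d",
      worst, STATE_NAMES[idx[2]], idx[1]))
  }
  pmin(pmax(states, lo), hi)
}

newTrajectory <- function(times, states, params, triggerTime = NA_real_) {
  structure(list(times = as.numeric(times), states = states,
                 params = params, triggerTime = triggerTime),
            class = "meio_trajectory")
}

#' @export
print.meio_trajectory <- function(x, ...) {
  cat(sprintf("Model trajectory: %d samples over [%g, %g] min\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  if (!is.na(x$triggerTime))
    cat(sprintf("  GVBD trigger applied at t = %g min\n", x$triggerTime))
  k <- nrow(x$states)
  cat("  final state:\n")
  print(round(x$states[k, ], 5))
  invisible(x)
}

#' Trajectory as a data frame
#'
#' One row per sample: `time` (minutes), the six state components, and the
#' four conserved complements (`Cdc25`, `Wee1p`, `Cdk1p`, `Cdh1p`).
#'
#' @param x a `meio_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data.frame.
#' @export
as.data.frame.meio_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  comp <- t(apply(x$states, 1, function(s)
    complements(s, x$params, check = FALSE)))
  data.frame(time = x$times, x$states, comp)
}

#' Write a trajectory to CSV
#'
#' Columns: time (minutes), the six state variables, the four conserved
#' complements. Header row always written.
#'
#' @param trajectory a `meio_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

## Linear interpolation of one state column at time t.
trajAt <- function(trajectory, column, t) {
  stats::approx(trajectory$times, trajectory$states[, column], xout = t,
                rule = 2)$y
}
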