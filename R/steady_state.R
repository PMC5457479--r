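#' Numerical Jacobian of the model right-hand side
#'
#' Central finite differences with per-component step
#' `1e-7 * max(1, |x|)`; symmetric perturbation; deterministic.
#'
#' @param state named state vector (may sit slightly outside the bounds).
#' @param params a `meio_params` parameter set.
#' @return 6x6 matrix of partial derivatives (per minute), rows and
#'   columns in state order.
#' @export
modelJacobian <- function(state, params) {
  s <- state[STATE_NAMES]
  J <- matrix(NA_real_, 6, 6, dimnames = list(STATE_NAMES, STATE_NAMES))
  for (k in seq_len(6)) {
    h <- 1e-7 * max(1, abs(s[[k]]))
    sp <- s; sm <- s
    sp[k] <- s[[k]] + h
    sm[k] <- s[[k]] - h
    J[, k] <- (modelDerivatives(sp, params) -
                 modelDerivatives(sm, params)) / (2 * h)
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries")
  J
}

newSteadyState <- function(state, params, eig, marginalTol = 1e-8) {
  res <- max(abs(modelDerivatives(state, params)))
  re <- Re(eig)
  marginal <- any(abs(re) <= marginalTol)
  stability <- if (marginal) "marginal"
    else if (all(re < -marginalTol)) "stable" else "unstable"
  structure(list(state = state, residualNorm = res, stability = stability,
                 eigenvalues = eig, marginal = marginal, params = params),
            class = "meio_steady")
}

#' @export
print.meio_steady <- function(x, ...) {
  cat(sprintf("Steady state (%s%s), residual %.2e:\n", x$stability,
              if (x$marginal) ", marginal eigenvalue" else "",
              x$residualNorm))
  print(round(x$state, 6))
  cat("  leading eigenvalue Re:", format(max(Re(x$eigenvalues))), "\n")
  invisible(x)
}

## Damped Newton on the full 6-d system. Returns the polished state or
## NULL. Iterates are confined to a generous box to keep the Michaelis
## denominators away from their poles.
fullNewton <- function(state, params, tol = 1e-12, maxit = 80) {
  ## box keeps the Michaelis denominators (Jwee, J25 = 0.01) off their poles
  lo <- rep(-0.005, 6)
  hi <- c(3, 3, params[["Cdh1T"]] + 0.05, 3, 3, params[["Wee1T"]] + 0.005)
  x <- state[STATE_NAMES]
  fx <- tryCatch(modelDerivatives(x, params), error = function(e) NULL)
  if (is.null(fx) || any(!is.finite(fx))) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) return(x)
    J <- tryCatch(modelJacobian(x, params), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- pmin(pmax(x - lam * step, lo), hi)
      fn <- tryCatch(modelDerivatives(xn, params),
                     error = function(e) rep(NA_real_, 6))
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) break
      lam <- lam / 2
      if (lam < 1e-12) return(if (max(abs(fx)) < 1e-9) x else NULL)
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) < 1e-9) x else NULL
}

#' Polish and classify a steady-state candidate
#'
#' Newton-polishes a near-equilibrium state to residual infinity-norm
#' below 1e-9, then classifies its linear stability from the eigenvalues
#' of the finite-difference Jacobian. Stability is `"stable"` iff all
#' eigenvalue real parts are below -1e-8, `"unstable"` if any exceeds
#' +1e-8; eigenvalues with `|Re| <= 1e-8` yield the honest label
#' `"marginal"` rather than a silent call either way.
#'
#' @param state candidate state with residual infinity-norm below 1e-3
#'   (loose enough to admit equilibria quoted to 4 significant figures,
#'   whose rounding alone leaves a residual of order 1e-4).
#' @param params a `meio_params` parameter set.
#' @return a `meio_steady`: list with `state`, `residualNorm`,
#'   `stability`, `eigenvalues`, `marginal`.
#' @export
classifySteadyState <- function(state, params) {
  res0 <- max(abs(modelDerivatives(state, params)))
  if (res0 >= 1e-3)
    stop(sprintf(
      "not a steady-state candidate: residual norm %.3g >= 1e-3", res0))
  x <- fullNewton(state, params)
  if (is.null(x)) stop("Newton polish diverged; candidate rejected")
  eig <- eigen(modelJacobian(x, params), only.values = TRUE)$values
  newSteadyState(x, params, eig)
}

#' Enumerate all steady states of the full system
#'
#' Multi-start root finding: seeds are laid on a regular grid over the
#' reduced `(Cdk1, Cdh1)` plane (`Cdk1` in \eqn{[0, cdk1Max]}, `Cdh1` in
#' \eqn{[0, Cdh1T]}), lifted to full states through the pseudo-steady-state
#' map of [liftState()] (with `Cdk1` clamped to the lifted `CycBT`), and
#' polished by a damped Newton iteration. Converged roots are kept when
#' they lie in the admissible region (components within their bounds, with
#' 1e-6 slack), deduplicated at 1e-6 per component, classified, and sorted
#' by Cdh1 descending (GV-like state first).
#'
#' @param params a `meio_params` parameter set.
#' @param grid number of seeds per axis (default 15; the steady-state
#'   count for the reference parameter sets is insensitive to the density
#'   from 15x15 up).
#' @param cdk1Max upper end of the Cdk1 seed range (default 1.2; cyclin
#'   totals self-limit near `ksCycB/kd1CycB` = 1).
#' @return list of `meio_steady` objects (possibly empty, with a warning,
#'   if no start converged).
#' @examples
#' \donttest{
#' ss <- findSteadyStates(meioParams())
#' length(ss)  # 3: stable GV arrest, unstable saddle, stable prometaphase
#' }
#' @export
findSteadyStates <- function(params, grid = 15, cdk1Max = 1.2) {
  validateParams(params)
  cdh1T <- params[["Cdh1T"]]
  seeds <- expand.grid(
    Cdk1 = seq(0, cdk1Max, length.out = grid),
    Cdh1 = seq(0, cdh1T, length.out = grid)
  )
  found <- matrix(numeric(0), 0, 6)
  for (i in seq_len(nrow(seeds))) {
    st <- liftState(seeds$Cdk1[i], seeds$Cdh1[i], params)
    st[["Cdk1"]] <- min(st[["Cdk1"]], st[["CycBT"]])
    x <- fullNewton(st, params)
    if (is.null(x)) next
    if (!admissibleRoot(x, params)) next
    if (!nrow(found) ||
        min(apply(abs(found - rep(x, each = nrow(found))), 1, max)) > 1e-6)
      found <- rbind(found, x)
  }
  if (!nrow(found)) {
    warning("no steady state converged in the search region")
    return(list())
  }
  out <- lapply(seq_len(nrow(found)), function(i) {
    s <- stats::setNames(found[i, ], STATE_NAMES)
    eig <- eigen(modelJacobian(s, params), only.values = TRUE)$values
    newSteadyState(s, params, eig)
  })
  out[order(-vapply(out, function(s) s$state[["Cdh1"]], numeric(1)))]
}

admissibleRoot <- function(x, params, tol = 1e-6) {
  all(x >= -tol) &&
    x[2] <= x[1] + tol &&
    x[3] <= params[["Cdh1T"]] + tol &&
    x[5] <= x[4] + tol &&
    x[6] <= params[["Wee1T"]] + tol
}

#' Steady-state report as a data frame
#'
#' One row per steady state: the six components, the residual norm, the
#' stability label and the leading eigenvalue real part.
#'
#' @param steadyStates list of `meio_steady` objects, as returned by
#'   [findSteadyStates()].
#' @return a data.frame.
#' @export
steadyStateTable <- function(steadyStates) {
  rows <- lapply(steadyStates, function(s) {
    data.frame(t(s$state), residual = s$residualNorm,
               stability = s$stability,
               leadingEigRe = max(Re(s$eigenvalues)))
  })
  do.call(rbind, rows)
}
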