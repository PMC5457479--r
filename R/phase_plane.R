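#' Lift a point of the reduced plane to a full model state
#'
#' The two-dimensional reduction treats Cdk1 and Cdh1 as the slow dynamic
#' variables and places the remaining four at their pseudo-steady states:
#' \itemize{
#'   \item `CycBT = ksCycB / (kd1CycB + kd2CycB * cdh1)` (synthesis =
#'     degradation);
#'   \item `Cdc25T = ksc25 / (kd1c25 + kd2c25 * cdh1)`;
#'   \item `Wee1 = Wee1T * GK(VaWee, ViWee * cdk1, Jwee/Wee1T, Jwee/Wee1T)`
#'     — a pure Goldbeter-Koshland balance (see [goldbeterKoshland()]);
#'   \item `Cdc25p`: root of the full scalar balance `activation =
#'     inactivation + degradation`, i.e.
#'     `Va25*cdk1*(Cdc25T - Cdc25p)/(J25 + Cdc25T - Cdc25p) =
#'      Vi25*Cdc25p/(J25 + Cdc25p) + (kd1c25 + kd2c25*cdh1)*Cdc25p`,
#'     solved by bracketed root finding on `[0, Cdc25T]` (the degradation
#'     sink makes the pure closed form inexact here).
#' }
#'
#' @param cdk1,cdh1 coordinates in the reduced plane (nonnegative scalars).
#' @param params a `meio_params` parameter set.
#' @return a named state vector. If the point leaves the admissible region
#'   (`cdk1 > CycBT(cdh1)`), the state carries attribute
#'   `outOfRegion = TRUE`; the caller decides what to do with it.
#' @export
liftState <- function(cdk1, cdh1, params) {
  cdk1 <- unname(cdk1); cdh1 <- unname(cdh1)
  if (!is.finite(cdk1) || !is.finite(cdh1) || cdk1 < 0 || cdh1 < 0)
    stop("cdk1 and cdh1 must be finite and nonnegative")
  p <- as.list(unclass(params))
  cycBT <- p$ksCycB / (p$kd1CycB + p$kd2CycB * cdh1)
  cdc25T <- p$ksc25 / (p$kd1c25 + p$kd2c25 * cdh1)
  wee1 <- p$Wee1T * goldbeterKoshland(p$VaWee, p$ViWee * cdk1,
                                      p$Jwee / p$Wee1T, p$Jwee / p$Wee1T)
  cdc25p <- solveCdc25p(cdk1, cdh1, cdc25T, p)
  state <- c(CycBT = cycBT, Cdk1 = cdk1, Cdh1 = cdh1,
             Cdc25T = cdc25T, Cdc25p = cdc25p, Wee1 = wee1)
  if (cdk1 > cycBT) attr(state, "outOfRegion") <- TRUE
  state
}

## Scalar pseudo-steady-state balance for Cdc25p on [0, Cdc25T]; the
## residual is strictly decreasing in Cdc25p, so the root is unique.
solveCdc25p <- function(cdk1, cdh1, cdc25T, p) {
  deg <- p$kd1c25 + p$kd2c25 * cdh1
  bal <- function(x) {
    c25 <- cdc25T - x
    p$Va25 * cdk1 * c25 / (p$J25 + c25) -
      p$Vi25 * x / (p$J25 + x) - deg * x
  }
  if (cdk1 == 0 || cdc25T == 0) return(0)
  hi <- bal(cdc25T)
  if (hi >= 0) return(cdc25T)
  stats::uniroot(bal, c(0, cdc25T), tol = 1e-15)$root
}

newNullcline <- function(which, points, branch = rep(1L, nrow(points))) {
  structure(list(which = which, points = points, branch = branch),
            class = "meio_nullcline")
}

#' @export
print.meio_nullcline <- function(x, ...) {
  cat(sprintf("%s nullcline: %d points, %d branch(es)\n",
              x$which, nrow(x$points), length(unique(x$branch))))
  invisible(x)
}

#' Cdh1 nullcline of the reduced model
#'
#' The steady-state activity of APC/C-Cdh1 as a function of active Cdk1: a
#' sigmoidal decreasing Goldbeter-Koshland curve, single-valued,
#' `Cdh1 = Cdh1T * GK(VaCdh1, ViCdh1*Cdk1, JCdh1/Cdh1T, JCdh1/Cdh1T)`.
#'
#' @param params a `meio_params` parameter set.
#' @param cdk1Grid increasing grid of Cdk1 values (default 201 points over
#'   \eqn{[0, 1.2]}).
#' @return a `meio_nullcline` with ordered `(Cdk1, Cdh1)` points.
#' @export
cdh1Nullcline <- function(params, cdk1Grid = seq(0, 1.2, length.out = 201)) {
  validateParams(params)
  if (is.unsorted(cdk1Grid, strictly = TRUE))
    stop("cdk1Grid must be strictly increasing")
  p <- as.list(unclass(params))
  cdh1 <- p$Cdh1T * goldbeterKoshland(p$VaCdh1, p$ViCdh1 * cdk1Grid,
                                      p$JCdh1 / p$Cdh1T, p$JCdh1 / p$Cdh1T)
  newNullcline("cdh1_balance",
               cbind(Cdk1 = cdk1Grid, Cdh1 = cdh1))
}

## Reduced Cdh1 balance as a function: cdh1 = h(cdk1).
cdh1BalanceFun <- function(params) {
  p <- as.list(unclass(params))
  function(cdk1)
    p$Cdh1T * goldbeterKoshland(p$VaCdh1, p$ViCdh1 * cdk1,
                                p$JCdh1 / p$Cdh1T, p$JCdh1 / p$Cdh1T)
}

## Cdk1 component of the full RHS evaluated on the lifted state.
cdk1BalanceResidual <- function(cdk1, cdh1, params) {
  st <- liftState(cdk1, cdh1, params)
  modelDerivatives(st, params)[["Cdk1"]]
}

#' Cdk1 nullcline of the reduced model
#'
#' For each Cdh1 value of the scan grid, all roots in Cdk1 of the lifted
#' Cdk1 balance (the Cdk1 component of [modelDerivatives()] on the
#' pseudo-steady-state lift) are enumerated by dense sign-change bracketing
#' over \eqn{[0, CycBT(Cdh1)]} followed by bisection. The curve is
#' S-shaped (up to 3 roots per Cdh1) in the bistable regime; branch labels
#' are assigned by root rank within each scan line (lower/middle/upper in
#' Cdk1), which is contiguous for an S-shaped curve.
#'
#' @param params a `meio_params` parameter set.
#' @param cdh1Grid grid of Cdh1 values covering \eqn{[0, Cdh1T]} (default
#'   161 points).
#' @param nBrackets number of brackets for the root scan (default 400).
#' @return a `meio_nullcline`; `points` holds one `(Cdk1, Cdh1)` row per
#'   root found, `branch` the branch labels. Even-multiplicity tangencies
#'   (bracket endpoints of equal sign with an interior extremum crossing
#'   zero) are resolved by splitting at the extremum; unresolved tangencies
#'   are flagged via attribute `tangency`.
#' @export
cdk1Nullcline <- function(params,
                          cdh1Grid = seq(0, params[["Cdh1T"]],
                                         length.out = 161),
                          nBrackets = 400) {
  validateParams(params)
  pts <- list(); br <- integer(0)
  prevRoots <- numeric(0); prevLabels <- integer(0); nextLabel <- 1L
  for (cdh1 in cdh1Grid) {
    roots <- cdk1BalanceRoots(cdh1, params, nBrackets)
    if (!length(roots)) { prevRoots <- numeric(0); prevLabels <- integer(0); next }
    ## nearest-neighbour continuity in Cdk1 against the previous scan line
    labels <- integer(length(roots))
    for (k in seq_along(roots)) {
      if (length(prevRoots)) {
        j <- which.min(abs(prevRoots - roots[k]))
        cand <- prevLabels[j]
        if (abs(prevRoots[j] - roots[k]) < 0.15 && !(cand %in% labels[seq_len(k - 1)])) {
          labels[k] <- cand
          next
        }
      }
      labels[k] <- nextLabel
      nextLabel <- nextLabel + 1L
    }
    pts[[length(pts) + 1L]] <- cbind(Cdk1 = roots, Cdh1 = cdh1)
    br <- c(br, labels)
    prevRoots <- roots; prevLabels <- labels
  }
  points <- do.call(rbind, pts)
  newNullcline("cdk1_balance", points, br)
}

## All roots of the lifted Cdk1 balance in [0, CycBT(cdh1)].
cdk1BalanceRoots <- function(cdh1, params, nBrackets = 400) {
  p <- as.list(unclass(params))
  cycBT <- p$ksCycB / (p$kd1CycB + p$kd2CycB * cdh1)
  grid <- seq(0, cycBT, length.out = nBrackets + 1)
  f <- vapply(grid, cdk1BalanceResidual, numeric(1),
              cdh1 = cdh1, params = params)
  roots <- numeric(0)
  for (i in seq_len(nBrackets)) {
    if (f[i] == 0) { roots <- c(roots, grid[i]); next }
    if (f[i] * f[i + 1] < 0) {
      r <- stats::uniroot(cdk1BalanceResidual, c(grid[i], grid[i + 1]),
                          cdh1 = cdh1, params = params, tol = 1e-13)$root
      roots <- c(roots, r)
    }
  }
  if (f[nBrackets + 1] == 0) roots <- c(roots, grid[nBrackets + 1])
  sort(unique(roots))
}

#' Intersections of two nullclines
#'
#' Candidate crossings are detected by segment-pair intersection between
#' the polylines (per branch), then polished by a damped two-dimensional
#' Newton iteration on the reduced balance system (the Cdk1 and Cdh1
#' components of [modelDerivatives()] on the lifted state). Duplicates
#' within 1e-6 are merged.
#'
#' @param n1,n2 `meio_nullcline` objects computed under `params`.
#' @param params a `meio_params` parameter set.
#' @return a matrix with columns `Cdk1`, `Cdh1`, one row per intersection
#'   (possibly zero rows), sorted by Cdh1 descending.
#' @export
nullclineIntersections <- function(n1, n2, params) {
  seeds <- segmentCrossings(n1, n2)
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("Cdk1", "Cdh1")))
  for (i in seq_len(nrow(seeds))) {
    sol <- reducedNewton(seeds[i, 1], seeds[i, 2], params)
    if (is.null(sol)) next
    if (!nrow(out) ||
        min(apply(abs(out - rep(sol, each = nrow(out))), 1, max)) > 1e-6)
      out <- rbind(out, sol)
  }
  out[order(-out[, "Cdh1"]), , drop = FALSE]
}

## Brute segment-pair crossing scan between two polylines (branch-wise).
segmentCrossings <- function(n1, n2) {
  segs <- function(n) {
    ord <- order(n$branch, n$points[, "Cdh1"], n$points[, "Cdk1"])
    pts <- n$points[ord, , drop = FALSE]
    b <- n$branch[ord]
    keep <- which(diff(b) == 0)
    cbind(pts[keep, , drop = FALSE], pts[keep + 1, , drop = FALSE])
  }
  s1 <- segs(n1); s2 <- segs(n2)
  hits <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(s1))) {
    a <- s1[i, 1:2]; b <- s1[i, 3:4]
    d1 <- b - a
    for (j in seq_len(nrow(s2))) {
      c_ <- s2[j, 1:2]; d <- s2[j, 3:4]
      d2 <- d - c_
      den <- d1[1] * d2[2] - d1[2] * d2[1]
      if (abs(den) < 1e-14) next
      t <- ((c_[1] - a[1]) * d2[2] - (c_[2] - a[2]) * d2[1]) / den
      u <- ((c_[1] - a[1]) * d1[2] - (c_[2] - a[2]) * d1[1]) / den
      if (t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9)
        hits <- rbind(hits, a + t * d1)
    }
  }
  hits
}

## Damped Newton on the reduced 2-d balance; returns c(Cdk1, Cdh1) or NULL.
reducedNewton <- function(cdk1, cdh1, params, tol = 1e-11, maxit = 60) {
  F <- function(x) {
    st <- liftState(max(x[1], 0), max(x[2], 0), params)
    d <- modelDerivatives(st, params)
    c(d[["Cdk1"]], d[["Cdh1"]])
  }
  x <- c(cdk1, cdh1)
  fx <- F(x)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol)
      return(stats::setNames(pmax(x, 0), c("Cdk1", "Cdh1")))
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      h <- 1e-7 * max(1, abs(x[k]))
      xp <- x; xm <- x
      xp[k] <- x[k] + h; xm[k] <- max(x[k] - h, 0)
      J[, k] <- (F(xp) - F(xm)) / (xp[k] - xm[k])
    }
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- pmax(x - lam * step, 0)
      fn <- tryCatch(F(xn), error = function(e) rep(NA_real_, 2))
      if (all(is.finite(fn)) && max(abs(fn)) < max(abs(fx))) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) < tol)
    return(stats::setNames(pmax(x, 0), c("Cdk1", "Cdh1")))
  NULL
}

#' Write a nullcline to CSV
#'
#' Columns: `which`, `branch`, `Cdk1`, `Cdh1`.
#'
#' @param nullcline a `meio_nullcline`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNullcline <- function(nullcline, path) {
  df <- data.frame(which = nullcline$which, branch = nullcline$branch,
                   Cdk1 = nullcline$points[, "Cdk1"],
                   Cdh1 = nullcline$points[, "Cdh1"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
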