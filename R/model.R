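#' Validate a model state vector
#'
#' A state holds the six dynamic variables: total cyclin B `CycBT`, active
#' cyclin B:Cdk1 `Cdk1`, active APC/C-Cdh1 `Cdh1`, total Cdc25B `Cdc25T`,
#' active phosphorylated Cdc25B `Cdc25p`, and active Wee1B `Wee1`. Bound
#' invariants: `0 <= Cdk1 <= CycBT`, `0 <= Cdh1 <= Cdh1T`,
#' `0 <= Cdc25p <= Cdc25T`, `0 <= Wee1 <= Wee1T`.
#'
#' @param state named numeric vector with the six state components.
#' @param params a `meio_params` parameter set (supplies the totals).
#' @param tol slack allowed on each bound; evaluation slightly outside the
#'   admissible region is needed for finite-difference Jacobians, so the
#'   default is permissive. Use `tol = 0` for a hard check.
#' @return the state, invisibly; errors name the violated bound.
#' @export
validateState <- function(state, params, tol = 1e-6) {
  missing <- setdiff(STATE_NAMES, names(state))
  if (length(missing))
    stop("missing state component(s): ", paste(missing, collapse = ", "))
  s <- state[STATE_NAMES]
  if (any(!is.finite(s)))
    stop("non-finite state component(s): ",
         paste(STATE_NAMES[!is.finite(s)], collapse = ", "))
  lo <- c(CycBT = 0, Cdk1 = 0, Cdh1 = 0, Cdc25T = 0, Cdc25p = 0, Wee1 = 0)
  hi <- c(CycBT = Inf, Cdk1 = s[["CycBT"]], Cdh1 = params[["Cdh1T"]],
          Cdc25T = Inf, Cdc25p = s[["Cdc25T"]], Wee1 = params[["Wee1T"]])
  bad <- STATE_NAMES[s < lo - tol | s > hi + tol]
  if (length(bad))
    stop("state bound violated for: ", paste(bad, collapse = ", "))
  invisible(state)
}

#' Conserved complements of a state
#'
#' The four algebraic mass-conservation relations of the model: inactive
#' Cdc25B `Cdc25 = Cdc25T - Cdc25p`, inactive (phosphorylated) Wee1B
#' `Wee1p = Wee1T - Wee1`, inhibited (Y15-phosphorylated) complex
#' `Cdk1p = CycBT - Cdk1`, and inactive Cdh1 `Cdh1p = Cdh1T - Cdh1`.
#' Exact subtractions, no tolerance.
#'
#' @inheritParams validateState
#' @param check if `TRUE` (default), error when a complement is negative
#'   beyond round-off, naming the offending pair.
#' @return named numeric vector `c(Cdc25, Wee1p, Cdk1p, Cdh1p)`.
#' @examples
#' complements(gvArrestState(), meioParams())
#' @export
complements <- function(state, params, check = TRUE) {
  comp <- c(
    Cdc25 = state[["Cdc25T"]] - state[["Cdc25p"]],
    Wee1p = params[["Wee1T"]] - state[["Wee1"]],
    Cdk1p = state[["CycBT"]] - state[["Cdk1"]],
    Cdh1p = params[["Cdh1T"]] - state[["Cdh1"]]
  )
  if (check && any(comp < -1e-9)) {
    pair <- c(Cdc25 = "Cdc25p > Cdc25T", Wee1p = "Wee1 > Wee1T",
              Cdk1p = "Cdk1 > CycBT", Cdh1p = "Cdh1 > Cdh1T")
    stop("negative conserved complement: ",
         paste(pair[names(comp)[comp < -1e-9]], collapse = "; "))
  }
  comp
}

#' Time derivatives of the six-variable model
#'
#' The model couples cyclin B synthesis and APC/C-Cdh1-dependent
#' degradation to the Wee1B/Cdc25B phosphorylation switch on Cdk1:
#'
#' \deqn{CycBT' = ksCycB - (kd1CycB + kd2CycB \cdot Cdh1) \cdot CycBT}
#' \deqn{Cdk1' = ksCycB - (kd1CycB + kd2CycB \cdot Cdh1) Cdk1
#'   - (Vi2CDK \cdot Wee1 + Vi1CDK \cdot Wee1p) Cdk1
#'   + (Va2CDK \cdot Cdc25p + Va1CDK \cdot Cdc25) Cdk1p}
#' \deqn{Cdh1' = VaCdh1 \cdot Cdh1p/(JCdh1 + Cdh1p)
#'   - ViCdh1 \cdot Cdk1 \cdot Cdh1/(JCdh1 + Cdh1)}
#' \deqn{Cdc25T' = ksc25 - (kd1c25 + kd2c25 \cdot Cdh1) \cdot Cdc25T}
#' \deqn{Cdc25p' = Va25 \cdot Cdk1 \cdot Cdc25/(J25 + Cdc25)
#'   - Vi25 \cdot Cdc25p/(J25 + Cdc25p)
#'   - (kd1c25 + kd2c25 \cdot Cdh1) \cdot Cdc25p}
#' \deqn{Wee1' = VaWee \cdot Wee1p/(JWee + Wee1p)
#'   - ViWee \cdot Wee1 \cdot Cdk1/(JWee + Wee1)}
#'
#' with the four conserved complements of [complements()] substituted
#' algebraically. Deterministic; does not mutate its inputs. Evaluation
#' slightly outside the state bounds is permitted (needed for numerical
#' Jacobians); only non-finite inputs are rejected.
#'
#' @inheritParams validateState
#' @return named numeric vector of the six time derivatives (per minute),
#'   in state order.
#' @examples
#' modelDerivatives(gvArrestState(), meioParams())  # ~0: GV arrest
#' @export
modelDerivatives <- function(state, params) {
  if (any(!is.finite(state[STATE_NAMES])))
    stop("non-finite state component(s): ",
         paste(STATE_NAMES[!is.finite(state[STATE_NAMES])], collapse = ", "))
  d <- rhsCore(unname(state[STATE_NAMES]),
               unname(unclass(params)[PARAM_NAMES]))
  stats::setNames(d, STATE_NAMES)
}

## Unnamed hot-path RHS: y in state order, p in PARAM_NAMES order. Kept
## free of naming/validation so the integrator can call it cheaply; the
## transcribed equations live here, once.
rhsCore <- function(y, p) {
  CycBT <- y[1]; Cdk1 <- y[2]; Cdh1 <- y[3]
  Cdc25T <- y[4]; Cdc25p <- y[5]; Wee1 <- y[6]
  Cdc25 <- Cdc25T - Cdc25p
  Wee1p <- p[12] - Wee1
  Cdk1p <- CycBT - Cdk1
  Cdh1p <- p[8] - Cdh1
  degCycB <- p[20] + p[21] * Cdh1
  degC25 <- p[17] + p[18] * Cdh1
  c(
    p[19] - degCycB * CycBT,
    p[19] - degCycB * Cdk1 -
      (p[4] * Wee1 + p[3] * Wee1p) * Cdk1 +
      (p[2] * Cdc25p + p[1] * Cdc25) * Cdk1p,
    p[5] * Cdh1p / (p[7] + Cdh1p) - p[6] * Cdk1 * Cdh1 / (p[7] + Cdh1),
    p[16] - degC25 * Cdc25T,
    p[13] * Cdk1 * Cdc25 / (p[15] + Cdc25) -
      p[14] * Cdc25p / (p[15] + Cdc25p) - degC25 * Cdc25p,
    p[9] * Wee1p / (p[11] + Wee1p) - p[10] * Wee1 * Cdk1 / (p[11] + Wee1)
  )
}

#' Goldbeter-Koshland steady-state active fraction
#'
#' Closed-form steady state of a covalent modification cycle with
#' Michaelis-Menten activation and inactivation: the unique root in
#' \eqn{[0, 1]} of
#' \deqn{Va (1 - f)/(Ja + 1 - f) = Vi \, f/(Ji + f).}
#' This is the zero-order-ultrasensitivity switch underlying the
#' pseudo-steady-state reduction of Wee1 and Cdh1. The quadratic
#' \eqn{(Vi - Va) f^2 - B f + Va\,Ji = 0}, \eqn{B = Vi - Va + Va\,Ji +
#' Vi\,Ja}, is solved in the product form \eqn{f = 2\,Va\,Ji / (B +
#' \sqrt{B^2 - 4 (Vi - Va) Va\,Ji})}, which is free of catastrophic
#' cancellation for every sign of \eqn{Vi - Va} (the square root always
#' exceeds \eqn{-B}).
#'
#' @param Va,Vi activation and inactivation rates (nonnegative, not both
#'   zero).
#' @param Ja,Ji activation and inactivation Michaelis constants relative to
#'   the total substrate (strictly positive).
#' @return the active fraction, a number in \eqn{[0, 1]}. Vectorized over
#'   `Va` and `Vi`.
#' @examples
#' goldbeterKoshland(1, 1, 0.15, 0.15)  # symmetric balance: 0.5
#' @export
goldbeterKoshland <- function(Va, Vi, Ja, Ji) {
  if (any(Ja <= 0) || any(Ji <= 0))
    stop("Michaelis constants Ja, Ji must be strictly positive")
  if (any(Va < 0) || any(Vi < 0))
    stop("rates Va, Vi must be nonnegative")
  if (any(Va == 0 & Vi == 0))
    stop("degenerate balance: Va and Vi are both zero")
  B <- Vi - Va + Va * Ji + Vi * Ja
  disc <- B^2 - 4 * (Vi - Va) * Va * Ji
  f <- 2 * Va * Ji / (B + sqrt(disc))
  pmin(pmax(f, 0), 1)
}
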