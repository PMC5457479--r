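# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the balance equations are re-transcribed from
# scratch and solved by bracketing bisection.

# Bisection solver for the covalent-modification balance
# Va (1-f)/(Ja+1-f) = Vi f/(Ji+f) on [0, 1]; the residual is strictly
# decreasing in f, so plain interval halving converges unconditionally.
gkBisect <- function(Va, Vi, Ja, Ji, iters = 80) {
  g <- function(f) Va * (1 - f) / (Ja + 1 - f) - Vi * f / (Ji + f)
  lo <- 0; hi <- 1
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Hand-expanded right-hand side, written term by term from the model
# equations, independently of the package's vectorised implementation.
rhsByHand <- function(state, params) {
  P <- as.list(unclass(params)); S <- as.list(state)
  Cdc25 <- S$Cdc25T - S$Cdc25p
  Wee1p <- P$Wee1T - S$Wee1
  Cdk1p <- S$CycBT - S$Cdk1
  Cdh1p <- P$Cdh1T - S$Cdh1
  dCycBT <- P$ksCycB - P$kd1CycB * S$CycBT - P$kd2CycB * S$Cdh1 * S$CycBT
  dCdk1 <- P$ksCycB -
    P$kd1CycB * S$Cdk1 - P$kd2CycB * S$Cdh1 * S$Cdk1 -
    P$Vi2CDK * S$Wee1 * S$Cdk1 - P$Vi1CDK * Wee1p * S$Cdk1 +
    P$Va2CDK * S$Cdc25p * Cdk1p + P$Va1CDK * Cdc25 * Cdk1p
  dCdh1 <- P$VaCdh1 * Cdh1p / (P$JCdh1 + Cdh1p) -
    P$ViCdh1 * S$Cdk1 * S$Cdh1 / (P$JCdh1 + S$Cdh1)
  dCdc25T <- P$ksc25 - P$kd1c25 * S$Cdc25T - P$kd2c25 * S$Cdh1 * S$Cdc25T
  dCdc25p <- P$Va25 * S$Cdk1 * Cdc25 / (P$J25 + Cdc25) -
    P$Vi25 * S$Cdc25p / (P$J25 + S$Cdc25p) -
    P$kd1c25 * S$Cdc25p - P$kd2c25 * S$Cdh1 * S$Cdc25p
  dWee1 <- P$VaWee * Wee1p / (P$Jwee + Wee1p) -
    P$ViWee * S$Wee1 * S$Cdk1 / (P$Jwee + S$Wee1)
  c(CycBT = dCycBT, Cdk1 = dCdk1, Cdh1 = dCdh1,
    Cdc25T = dCdc25T, Cdc25p = dCdc25p, Wee1 = dWee1)
}

# Random admissible state under a parameter set (seeded by the caller).
randomState <- function(params) {
  cycBT <- runif(1, 0.05, 1)
  cdc25T <- runif(1, 0.01, 0.8)
  c(CycBT = cycBT,
    Cdk1 = runif(1, 0, cycBT),
    Cdh1 = runif(1, 0, params[["Cdh1T"]]),
    Cdc25T = cdc25T,
    Cdc25p = runif(1, 0, cdc25T),
    Wee1 = runif(1, 0, params[["Wee1T"]]))
}

printedGvState <- function() {
  c(CycBT = 0.1701, Cdk1 = 0.04000, Cdh1 = 0.9759,
    Cdc25T = 0.09295, Cdc25p = 0.001675, Wee1 = 0.9981)
}
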