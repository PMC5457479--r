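#' @keywords internal
"_PACKAGE"

## Canonical parameter and state variable orderings used throughout.
PARAM_NAMES <- c(
  "Va1CDK", "Va2CDK", "Vi1CDK", "Vi2CDK",
  "VaCdh1", "ViCdh1", "JCdh1", "Cdh1T",
  "VaWee", "ViWee", "Jwee", "Wee1T",
  "Va25", "Vi25", "J25",
  "ksc25", "kd1c25", "kd2c25",
  "ksCycB", "kd1CycB", "kd2CycB"
)

STATE_NAMES <- c("CycBT", "Cdk1", "Cdh1", "Cdc25T", "Cdc25p", "Wee1")

## Wild-type GV-arrest parameter set; time unit is minutes, concentrations
## are dimensionless. These are the model's reference conditions.
WT_PARAMS <- c(
  Va1CDK = 0.015, Va2CDK = 1.5, Vi1CDK = 0.015, Vi2CDK = 0.3,
  VaCdh1 = 1.5, ViCdh1 = 6, JCdh1 = 0.15, Cdh1T = 1,
  VaWee = 0.375, ViWee = 1.5, Jwee = 0.01, Wee1T = 1,
  Va25 = 1.5, Vi25 = 0.375, J25 = 0.01,
  ksc25 = 0.015, kd1c25 = 0.015, kd2c25 = 0.15,
  ksCycB = 0.015, kd1CycB = 0.015, kd2CycB = 0.075
)

#' Construct a model parameter set
#'
#' Returns the wild-type GV-arrest parameter set, optionally with named
#' overrides. All rates are per minute; Michaelis constants and protein
#' totals are dimensionless concentrations. Parameter sets are plain named
#' numeric vectors (class `meio_params`); scenario edits always produce
#' copies, never mutate.
#'
#' @param ... named numeric overrides, e.g. `Cdh1T = 0.05`. Unknown names
#'   are an error.
#' @return named numeric vector of the 21 model parameters, class
#'   `meio_params`.
#' @examples
#' p <- meioParams()
#' p["ksCycB"]
#' ko <- meioParams(Cdh1T = 0.05)
#' @export
meioParams <- function(...) {
  overrides <- c(...)
  p <- WT_PARAMS
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(overrides), PARAM_NAMES)
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- as.numeric(overrides)
  }
  validateParams(p)
  structure(p, class = "meio_params")
}

#' Validate a parameter set
#'
#' Checks that all 21 parameters are present, finite and nonnegative, and
#' that the totals (`Cdh1T`, `Wee1T`) and Michaelis constants (`JCdh1`,
#' `Jwee`, `J25`) are strictly positive.
#'
#' @param params named numeric vector of parameters.
#' @return the validated parameters, invisibly.
#' @export
validateParams <- function(params) {
  missing <- setdiff(PARAM_NAMES, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  v <- unclass(params)[PARAM_NAMES]
  if (any(!is.finite(v)))
    stop("non-finite parameter(s): ",
         paste(PARAM_NAMES[!is.finite(v)], collapse = ", "))
  if (any(v < 0))
    stop("negative parameter(s): ",
         paste(PARAM_NAMES[v < 0], collapse = ", "))
  strict <- c("Cdh1T", "Wee1T", "JCdh1", "Jwee", "J25")
  if (any(v[strict] <= 0))
    stop("parameter(s) must be strictly positive: ",
         paste(strict[v[strict] <= 0], collapse = ", "))
  invisible(params)
}

#' @export
print.meio_params <- function(x, ...) {
  cat("Model parameters (rates per minute, concentrations dimensionless):\n")
  print(unclass(x))
  invisible(x)
}

#' Printed wild-type GV-arrest state
#'
#' The resting (GV-arrest) state of the wild-type model: high APC/C-Cdh1,
#' low active Cdk1. This state is (to four significant figures) the stable
#' steady state of the wild-type system with highest Cdh1.
#'
#' @return named numeric state vector with components `CycBT`, `Cdk1`,
#'   `Cdh1`, `Cdc25T`, `Cdc25p`, `Wee1`.
#' @examples
#' gvArrestState()
#' @export
gvArrestState <- function() {
  c(CycBT = 0.1701, Cdk1 = 0.04000, Cdh1 = 0.9759,
    Cdc25T = 0.09295, Cdc25p = 0.001675, Wee1 = 0.9981)
}

#' Apply the GVBD trigger to a parameter set
#'
#' Meiotic resumption (loss of PKA activity after IBMX release) is modelled
#' as a partial collapse of the phosphorylation brake: the Wee1B activation
#' rate `VaWee` and the Cdc25B inactivation rate `Vi25` drop to 20% of their
#' wild-type values (both become 0.075 per minute). All other parameters
#' are untouched; the operation is idempotent.
#'
#' @param params a `meio_params` parameter set.
#' @return a modified copy of `params`.
#' @export
applyGvbdTrigger <- function(params) {
  validateParams(params)
  out <- params
  out["VaWee"] <- 0.075
  out["Vi25"] <- 0.075
  out
}

#' Apply a knockout override to a parameter set
#'
#' Knockouts retain residual activity rather than being zeroed: the Cdh1
#' knockout sets total Cdh1 `Cdh1T = 0.05`; the Cdc25B knockout sets the
#' Cdc25B synthesis rate `ksc25 = 0.0003`. The two compose (in either
#' order) to the double knockout.
#'
#' @param params a `meio_params` parameter set.
#' @param component `"cdh1"` or `"cdc25b"`.
#' @return a modified copy of `params`.
#' @export
applyKnockout <- function(params, component = c("cdh1", "cdc25b")) {
  validateParams(params)
  component <- match.arg(component)
  out <- params
  if (component == "cdh1") out["Cdh1T"] <- 0.05 else out["ksc25"] <- 0.0003
  out
}

SCENARIO_NAMES <- c("wild_type_gv", "wild_type_gvbd", "cdh1_ko",
                    "cdc25b_ko", "double_ko")

#' Parameter set for a named scenario
#'
#' Expands a scenario name into its parameter overrides: `wild_type_gv` is
#' the untouched wild-type set; `wild_type_gvbd` applies the GVBD trigger;
#' `cdh1_ko`, `cdc25b_ko` and `double_ko` compose the knockout override(s)
#' with the trigger (knockout oocytes are observed after release, so the
#' trigger applies).
#'
#' @param name one of `"wild_type_gv"`, `"wild_type_gvbd"`, `"cdh1_ko"`,
#'   `"cdc25b_ko"`, `"double_ko"`.
#' @param triggered logical; override whether the GVBD trigger is applied
#'   (default: `TRUE` for all scenarios except `wild_type_gv`).
#' @return a `meio_params` parameter set.
#' @export
scenarioParams <- function(name, triggered = NULL) {
  name <- match.arg(name, SCENARIO_NAMES)
  p <- meioParams()
  if (name %in% c("cdh1_ko", "double_ko")) p <- applyKnockout(p, "cdh1")
  if (name %in% c("cdc25b_ko", "double_ko")) p <- applyKnockout(p, "cdc25b")
  if (is.null(triggered)) triggered <- name != "wild_type_gv"
  if (triggered) p <- applyGvbdTrigger(p)
  p
}

#' Read a parameter set from a key-value file
#'
#' The file format is one `key = value` pair per line, `#` comments and
#' blank lines ignored; keys are exactly the model's parameter symbols. A
#' bundled file `system.file("extdata", "wt_params.conf", package =
#' "meioswitch")` reproduces the wild-type set.
#'
#' @param path file path.
#' @return a `meio_params` parameter set (wild-type values for any key not
#'   present in the file).
#' @export
readParams <- function(path) {
  kv <- readKeyValue(path)
  bad <- setdiff(names(kv), PARAM_NAMES)
  if (length(bad))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(meioParams, as.list(kv))
}

#' Write a parameter set to a key-value file
#'
#' @param params a `meio_params` parameter set.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeParams <- function(params, path) {
  validateParams(params)
  lines <- sprintf("%s = %s", PARAM_NAMES,
                   vapply(unclass(params)[PARAM_NAMES],
                          format, character(1), digits = 15))
  writeLines(lines, path)
  invisible(path)
}

## Parse a flat "key = value" file into a named numeric vector.
readKeyValue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed line (expected 'key = value'): ",
         lines[!grepl("=", lines, fixed = TRUE)][1])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  if (any(is.na(num)))
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(num)], collapse = ", "))
  stats::setNames(num, keys)
}
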