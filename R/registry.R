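#' Construct a PPLFER system-parameter set
#'
#' @param endpoint Endpoint code, see \code{\link{pplfer_endpoints}}.
#' @param coef Named numeric vector/list with elements
#'   \code{s, a, b, d, v, l, c} (log-unit scale).  \code{d} multiplies
#'   \code{sqrt(A*B)} and must be 0 for partition endpoints.
#' @param se Named numeric vector/list of per-coefficient standard
#'   errors (same names), all non-negative.
#' @param total_se Total standard error of the equation (log units).
#' @param units Units string; defaults to the endpoint's canonical
#'   units.
#' @param derived Optional provenance: \code{NULL} for calibrated rows,
#'   or a list \code{list(op = "sum"|"difference", of = c(e1, e2))} for
#'   rows defined by a thermodynamic property cycle.
#' @return Object of class \code{system_parameters}.
#' @examples
#' system_parameters("KAW",
#'   coef = c(s = -2.26, a = -3.72, b = -4.78, d = 0, v = 2.19,
#'            l = -0.38, c = 0.64),
#'   se = c(s = 0.05, a = 0.04, b = 0.04, d = 0, v = 0.06, l = 0.02,
#'          c = 0.03),
#'   total_se = 0.17)
#' @export
system_parameters <- function(endpoint, coef, se, total_se,
                              units = NULL, derived = NULL) {
  .check_endpoint(endpoint)
  nm <- c("s", "a", "b", "d", "v", "l", "c")
  coef <- unlist(coef)[nm]
  se <- unlist(se)[nm]
  names(coef) <- names(se) <- nm
  if (any(is.na(coef))) stop("coefficients must include s, a, b, d, v, l, c")
  if (any(is.na(se)) || any(se < 0))
    stop("standard errors must be non-negative and complete")
  if (!is.numeric(total_se) || total_se < 0)
    stop("total_se must be a non-negative number")
  if (!is_solubility_endpoint(endpoint) && coef[["d"]] != 0)
    stop("partition endpoint '", endpoint, "' must have d = 0")
  structure(
    list(endpoint = endpoint, coef = coef, se = se,
         total_se = as.numeric(total_se),
         units = if (is.null(units)) .endpoint_units(endpoint) else units,
         derived = derived),
    class = "system_parameters")
}

#' @export
print.system_parameters <- function(x, digits = 4, ...) {
  cat("PPLFER system parameters:", x$endpoint, "[", x$units, "]\n")
  m <- rbind(coef = x$coef, se = x$se)
  print(round(m, digits))
  cat("total s.e.:", format(x$total_se, digits = digits))
  if (!is.null(x$derived))
    cat("  (derived by cycle:", x$derived$op, "of",
        paste(x$derived$of, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

.registry_cache <- new.env(parent = emptyenv())

#' Bundled Table of PPLFER system parameters
#'
#' Loads the registry of system parameters for the nine supported
#' endpoints, as shipped with the package.  The calibrated rows (KAW,
#' KOA, wet KOW, liquid VP and SW) come from multiple linear regression
#' against experimental solute descriptors; the remaining rows (dry
#' KOW, KOO, dry/wet SO) are defined by thermodynamic property cycles
#' and are stored at the same 2-decimal precision they round-trip to.
#'
#' @param path Optional path to an alternative registry YAML file.
#' @return Named list of \code{system_parameters}, one per endpoint.
#' @seealso \code{\link{check_cycle_consistency}} to audit the cycle
#'   identities of a registry.
#' @export
pplfer_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$builtin)) return(.registry_cache$builtin)
    path <- system.file("extdata", "system_parameters.yaml",
                        package = "pplferkit", mustWork = TRUE)
    reg <- read_registry(path)
    .registry_cache$builtin <- reg
    return(reg)
  }
  read_registry(path)
}

#' Look up one endpoint in the bundled registry
#'
#' @param endpoint Endpoint code, one of \code{\link{pplfer_endpoints}}.
#' @return A \code{\link{system_parameters}} object.
#' @examples
#' builtin_system_parameters("KAW")$total_se  # 0.17
#' @export
builtin_system_parameters <- function(endpoint) {
  .check_endpoint(endpoint)
  pplfer_registry()[[endpoint]]
}

#' Read a system-parameter registry from YAML
#'
#' @param path Path to a YAML file with the schema used by
#'   \code{inst/extdata/system_parameters.yaml}: top-level
#'   \code{endpoints} mapping endpoint code to \code{coef}, \code{se},
#'   \code{total_se}, \code{units} and optional \code{derived}.
#' @return Named list of \code{system_parameters}.
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$endpoints)) stop("registry file has no 'endpoints' key")
  out <- lapply(names(raw$endpoints), function(ep) {
    r <- raw$endpoints[[ep]]
    system_parameters(ep, coef = r$coef, se = r$se,
                      total_se = r$total_se, units = r$units,
                      derived = r$derived)
  })
  names(out) <- names(raw$endpoints)
  out
}

#' Write a system-parameter registry to YAML
#'
#' Serialization inverse of \code{\link{read_registry}}: a registry
#' written and re-read preserves every value exactly.
#'
#' @param registry Named list of \code{system_parameters}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  eps <- lapply(registry, function(sp) {
    list(units = sp$units,
         coef = as.list(sp$coef),
         se = as.list(sp$se),
         total_se = sp$total_se,
         derived = sp$derived)
  })
  yaml::write_yaml(list(version = 1L, endpoints = eps), path,
                   precision = 15L)
  invisible(path)
}
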