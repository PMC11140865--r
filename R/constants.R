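#' Physical constants used throughout the package
#'
#' Returns the fixed physical constants: the ideal gas constant in
#' Pa m^3/(mol K) (numerically equal to J/(mol K)), the default system
#' temperature (25 C), standard atmospheric pressure, and the standard
#' normal quantile used for 95\% prediction intervals.
#'
#' @return A named list with elements \code{R} (8.314 Pa m^3/(mol K)),
#'   \code{T_default} (298.15 K), \code{P_atm} (101325 Pa) and
#'   \code{z95} (1.96).
#' @examples
#' physical_constants()$R
#' @export
physical_constants <- function() {
  list(R = 8.314, T_default = 298.15, P_atm = 101325, z95 = 1.96)
}

# internal shorthand; immutable by convention
.pc <- list(R = 8.314, T_default = 298.15, P_atm = 101325, z95 = 1.96)

#' Endpoints covered by the bundled system-parameter registry
#'
#' The nine property endpoints: air-water (\code{KAW}), octanol-air
#' (\code{KOA}), wet and dry octanol-water (\code{KOW_wet},
#' \code{KOW_dry}), the hypothetical wet/dry octanol ratio (\code{KOO}),
#' liquid vapor pressure (\code{VP_liquid}), and liquid-state
#' solubilities in water and in dry and wet octanol (\code{SW_liquid},
#' \code{SO_dry_liquid}, \code{SO_wet_liquid}).
#'
#' @return Character vector of endpoint codes.
#' @export
pplfer_endpoints <- function() {
  c("KAW", "KOA", "KOW_wet", "KOW_dry", "KOO",
    "VP_liquid", "SW_liquid", "SO_dry_liquid", "SO_wet_liquid")
}

# endpoints modelled with the solubility-form equation (d term present)
.solubility_endpoints <- c("VP_liquid", "SW_liquid",
                           "SO_dry_liquid", "SO_wet_liquid")

#' Test whether an endpoint uses the solubility-form PPLFER equation
#'
#' Solubility and vapor-pressure endpoints carry the extra
#' \code{d * sqrt(A * B)} self-interaction term; partition endpoints do
#' not.
#'
#' @param endpoint Endpoint code, see \code{\link{pplfer_endpoints}}.
#' @return Logical.
#' @export
is_solubility_endpoint <- function(endpoint) {
  endpoint %in% .solubility_endpoints
}

.endpoint_units <- function(endpoint) {
  switch(endpoint,
    VP_liquid = "log10(Pa)",
    SW_liquid = ,
    SO_dry_liquid = ,
    SO_wet_liquid = "log10(mol/L)",
    "log10(dimensionless ratio)")
}

.check_endpoint <- function(endpoint) {
  if (length(endpoint) != 1L || !endpoint %in% pplfer_endpoints())
    stop("unknown endpoint: ", paste(endpoint, collapse = ", "),
         "; must be one of ", paste(pplfer_endpoints(), collapse = ", "),
         call. = FALSE)
  endpoint
}
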