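# PPLFER equation evaluation.
#
# Partition form:  log K = s*S + a*A + b*B + v*V + l*L + c
# Solubility form: log S = s*S + a*A + b*B + d*sqrt(A*B) + v*V + l*L + c
# Both share one evaluation path; partition endpoints carry d = 0.

# evaluation-time check: arithmetic only needs finiteness and a
# well-defined sqrt(A*B); the stricter V > 0 constructor invariant is
# not required to evaluate the linear form (the V = 0 limit is the
# interaction-free intercept case)
.check_eval_descriptors <- function(sd) {
  for (f in c("S", "A", "B", "V", "L")) {
    val <- sd[[f]]
    if (is.null(val) || !is.numeric(val) || any(!is.finite(val)))
      stop("descriptor '", f, "' is missing or not finite", call. = FALSE)
  }
  if (any(sd[["A"]] < 0) || any(sd[["B"]] < 0))
    stop("descriptors 'A' and 'B' must be >= 0 (sqrt(A*B) undefined ",
         "otherwise)", call. = FALSE)
  invisible(sd)
}

.pplfer_value <- function(sp, sd) {
  .check_eval_descriptors(sd)
  co <- sp$coef
  co[["s"]] * sd[["S"]] + co[["a"]] * sd[["A"]] + co[["b"]] * sd[["B"]] +
    co[["d"]] * sqrt(sd[["A"]] * sd[["B"]]) +
    co[["v"]] * sd[["V"]] + co[["l"]] * sd[["L"]] + co[["c"]]
}

#' Evaluate the partition-form PPLFER equation
#'
#' Computes \code{log K = s*S + a*A + b*B + v*V + l*L + c} for a
#' partition endpoint.  No clipping or correction is applied.
#'
#' @param sp A \code{\link{system_parameters}} object for a partition
#'   endpoint (\code{d} must be 0).
#' @param sd Solute descriptors: a \code{\link{solute_descriptors}}
#'   object, named list, or data frame with columns
#'   \code{S, A, B, V, L} (vectorised over rows).
#' @return Numeric log10 partition ratio(s).
#' @examples
#' kow <- builtin_system_parameters("KOW_wet")
#' evaluate_partition(kow, list(S = 0, A = 0, B = 0, V = 0, L = 0))  # 0.41
#' @export
evaluate_partition <- function(sp, sd) {
  stopifnot(inherits(sp, "system_parameters"))
  if (is_solubility_endpoint(sp$endpoint) || sp$coef[["d"]] != 0)
    stop("evaluate_partition requires a partition endpoint (d = 0); got '",
         sp$endpoint, "'", call. = FALSE)
  .pplfer_value(sp, sd)
}

#' Evaluate the solubility-form PPLFER equation
#'
#' Computes
#' \code{log S = s*S + a*A + b*B + d*sqrt(A*B) + v*V + l*L + c} for a
#' vapor-pressure or solubility endpoint.  The \code{sqrt(A*B)} term
#' models hydrogen bonding between molecules of the solute in its own
#' pure phase and vanishes whenever \code{A} or \code{B} is zero.
#'
#' @inheritParams evaluate_partition
#' @param sp A \code{\link{system_parameters}} object for a VP or
#'   solubility endpoint.
#' @return Numeric log10 solubility (mol/L) or log10 vapor pressure
#'   (Pa), per \code{sp$units}.
#' @export
evaluate_solubility <- function(sp, sd) {
  stopifnot(inherits(sp, "system_parameters"))
  if (!is_solubility_endpoint(sp$endpoint))
    stop("evaluate_solubility requires a VP/solubility endpoint; got '",
         sp$endpoint, "'", call. = FALSE)
  .pplfer_value(sp, sd)
}

#' Per-solute system parameters for the solute's own liquid phase
#'
#' Container for the six coefficients of a PPLFER equation predicted
#' for the system "air / the solute's own pure liquid phase", used by
#' the indirect vapor-pressure route.  Coefficients for a specific
#' solute come from empirical regressions published elsewhere; this
#' package accepts them as inputs and does not refit them.
#'
#' @param s,a,b,v,l,c Finite numeric coefficients (log-unit scale).
#' @return Object of class \code{kkak_parameters}.
#' @export
kkak_parameters <- function(s, a, b, v, l, c) {
  x <- c(s = s, a = a, b = b, v = v, l = l, c = c)
  if (any(!is.finite(x))) stop("kkak coefficients must be finite")
  structure(as.list(x), class = "kkak_parameters")
}

#' Evaluate a K_kAk equation for a solute
#'
#' \code{log K_kAk}, the ratio between air and the solute's own pure
#' liquid phase, from caller-supplied per-solute coefficients.
#'
#' @param kp A \code{\link{kkak_parameters}} object.
#' @param sd Solute descriptors.
#' @return Numeric log10 K_kAk.
#' @export
evaluate_kkak <- function(kp, sd) {
  stopifnot(inherits(kp, "kkak_parameters"))
  .check_eval_descriptors(sd)
  kp$s * sd[["S"]] + kp$a * sd[["A"]] + kp$b * sd[["B"]] +
    kp$v * sd[["V"]] + kp$l * sd[["L"]] + kp$c
}

#' Vapor pressure from K_kAk by Raoult's law
#'
#' Rearranges Raoult's law, \code{VP = RT / (gamma * K_kAk * MV)}, to
#' log10 units: \code{log VP = log10(R*T) - log10(gamma) - log K_kAk -
#' log10(MV)} with the molar volume converted from L/mol to m^3/mol.
#' The activity coefficient of the solute in its own pure phase is
#' assumed to be unity by default.  This indirect route is only
#' validated for liquids; when \code{state} indicates a (possible)
#' solid the result carries a \code{"solid_indirect"} warning attribute
#' and a warning is emitted.
#'
#' @param log_kkak log10 K_kAk (air / own liquid phase).
#' @param MV Liquid molar volume (L/mol), > 0.
#' @param T System temperature (K), > 0.
#' @param gamma Activity coefficient in the pure phase, > 0.
#' @param state Optional predicted physical state; \code{"solid"} or
#'   \code{"maybe_solid"} triggers the reliability warning.
#' @return log10 vapor pressure (Pa).
#' @examples
#' vp_from_kkak(0, MV = 0.1)  # 7.394
#' @export
vp_from_kkak <- function(log_kkak, MV, T = .pc$T_default, gamma = 1,
                         state = NULL) {
  if (any(!is.finite(log_kkak))) stop("log_kkak must be finite")
  if (any(!is.finite(MV)) || any(MV <= 0)) stop("MV must be > 0")
  if (!is.finite(T) || T <= 0) stop("T must be > 0")
  if (any(!is.finite(gamma)) || any(gamma <= 0)) stop("gamma must be > 0")
  out <- log10(.pc$R * T) - log10(gamma) - log_kkak - log10(MV / 1000)
  if (!is.null(state) && any(state %in% c("solid", "maybe_solid"))) {
    warning("indirect VP route is only validated for liquids; ",
            "solute is predicted (maybe) solid", call. = FALSE)
    attr(out, "warning") <- "solid_indirect"
  }
  out
}

#' Convert log vapor pressure to log solubility in air
#'
#' Ideal-gas conversion at system temperature:
#' \code{log S_A = log VP - log10(1000 * R * T)}, giving mol/L.
#'
#' @param log_vp log10 vapor pressure (Pa).
#' @param T System temperature (K), > 0.
#' @return log10 solubility in air (mol/L).
#' @examples
#' vp_to_sa(log10(101325))  # -1.389 at 298.15 K
#' @export
vp_to_sa <- function(log_vp, T = .pc$T_default) {
  if (!is.finite(T) || T <= 0) stop("T must be > 0")
  log_vp - log10(1000 * .pc$R * T)
}
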