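# Physical-state handling: classification at system temperature, the
# Van't Hoff solid <-> supercooled-liquid conversion, and boundary
# caps on vapor pressure and solubility.

.states <- c("gas", "liquid", "maybe_solid", "solid", "unknown")

#' Classify the physical state of a solute at system temperature
#'
#' Transparent threshold rule on melting and boiling points: a solute
#' boiling at or below the system temperature is a gas; one melting at
#' least \code{margin} above it is a solid; one melting within
#' \code{margin} of it is flagged \code{maybe_solid}; one melting at
#' least \code{margin} below it (with a boiling point above system
#' temperature) is a liquid.  Missing inputs never raise an error: the
#' state is \code{unknown} when the rule cannot be decided.
#'
#' @param tp \code{\link{thermal_properties}} (or a list with
#'   \code{T_M}, \code{T_B} in K; \code{NA} when unknown).
#' @param T System temperature (K), default 298.15.
#' @param margin Half-width (K) of the \code{maybe_solid} band around
#'   the system temperature, default 10.
#' @return One of \code{"gas"}, \code{"liquid"}, \code{"maybe_solid"},
#'   \code{"solid"}, \code{"unknown"}.
#' @examples
#' classify_state(thermal_properties(T_M = 398.15, T_B = 550))  # solid
#' classify_state(thermal_properties(T_B = 250))                # gas
#' @export
classify_state <- function(tp, T = .pc$T_default, margin = 10) {
  if (!is.finite(T) || T <= 0) stop("T must be > 0")
  if (!is.finite(margin) || margin < 0) stop("margin must be >= 0")
  T_B <- suppressWarnings(as.numeric(tp[["T_B"]]))
  T_M <- suppressWarnings(as.numeric(tp[["T_M"]]))
  if (length(T_B) != 1L) T_B <- NA_real_
  if (length(T_M) != 1L) T_M <- NA_real_
  if (!is.na(T_B) && T_B <= T) return("gas")
  if (is.na(T_M)) return("unknown")
  if (T_M >= T + margin) return("solid")
  if (abs(T_M - T) < margin) return("maybe_solid")
  # T_M <= T - margin: liquid, but only if known not to boil below T
  if (!is.na(T_B) && T_B > T) return("liquid")
  "unknown"
}

#' Van't Hoff conversion between solid and supercooled-liquid values
#'
#' Fate and transport models work with the hypothetical supercooled
#' (subcooled) liquid state of solids.  The Van't Hoff approximation
#' relates the two states via the entropy of fusion and the melting
#' point:
#' \deqn{\log_{10} X_{solid} - \log_{10} X_{liquid} =
#'   -\Delta S_M (T_M - T) / (\ln(10) R T)}
#' for \eqn{T_M > T}; at or below the melting point no correction is
#' applied.  The same magnitude with opposite sign converts solid
#' values back to the supercooled liquid.
#'
#' @param log_value Property value in log10 units (VP or solubility).
#' @param dS_M Entropy of fusion (J/(mol K)), > 0.
#' @param T_M Melting point (K).
#' @param T System temperature (K), > 0.
#' @param direction \code{"liquid_to_solid"} (default) or
#'   \code{"solid_to_liquid"}.
#' @return Corrected log10 value.
#' @examples
#' vant_hoff_correct(0, dS_M = 56.5, T_M = 398.15)  # -0.990
#' @export
vant_hoff_correct <- function(log_value, dS_M, T_M,
                              T = .pc$T_default,
                              direction = c("liquid_to_solid",
                                            "solid_to_liquid")) {
  direction <- match.arg(direction)
  if (!is.finite(dS_M) || dS_M <= 0) stop("dS_M must be > 0")
  if (!is.finite(T) || T <= 0) stop("T must be > 0")
  if (!is.finite(T_M)) stop("T_M must be finite")
  shift <- if (T_M > T) -dS_M * (T_M - T) / (log(10) * .pc$R * T) else 0
  if (direction == "solid_to_liquid") shift <- -shift
  log_value + shift
}

#' Construct a property prediction record
#'
#' Light-weight container for one (solute, endpoint) prediction:
#' value, uncertainty level, RMSEP, 95\% prediction interval, predicted
#' state and provenance flags.
#'
#' @param endpoint Endpoint code (additionally \code{"SA"} is accepted
#'   for solubility in air).
#' @param value Predicted value (log10 units).
#' @param ul Integer uncertainty level 0-6, or \code{NA}.
#' @param rmsep Estimated RMSEP (log units), or \code{NA}.
#' @param pi_low,pi_high 95\% prediction-interval bounds; must be
#'   symmetric about \code{value}.
#' @param state Predicted physical state.
#' @param flags Character vector of provenance flags (subset of
#'   \code{capped}, \code{vant_hoff_applied}, \code{intercept_only},
#'   \code{uncalibrated_substructure}, \code{mv_fallback},
#'   \code{default_dS_M}).
#' @return Object of class \code{property_prediction}.
#' @export
property_prediction <- function(endpoint, value, ul = NA_integer_,
                                rmsep = NA_real_, pi_low = NA_real_,
                                pi_high = NA_real_, state = "unknown",
                                flags = character()) {
  if (!endpoint %in% c(pplfer_endpoints(), "SA"))
    stop("unknown endpoint: ", endpoint)
  if (!state %in% .states) stop("unknown state: ", state)
  if (!is.na(ul) && !(ul %in% 0:6)) stop("ul must be in 0..6 or NA")
  if (is.finite(pi_low) && is.finite(pi_high)) {
    if (pi_low > value || pi_high < value)
      stop("prediction interval must contain the value")
    if (abs((pi_high - value) - (value - pi_low)) > 1e-8)
      stop("prediction interval must be symmetric about the value")
  }
  structure(list(endpoint = endpoint, value = value, ul = ul,
                 rmsep = rmsep, pi_low = pi_low, pi_high = pi_high,
                 state = state, flags = unique(flags)),
            class = "property_prediction")
}

#' @export
print.property_prediction <- function(x, ...) {
  cat(sprintf("%s = %.3f  [UL %s, RMSEP %s, 95%% PI (%.3f, %.3f), %s]\n",
              x$endpoint, x$value,
              ifelse(is.na(x$ul), "-", x$ul),
              ifelse(is.na(x$rmsep), "-", sprintf("%.3f", x$rmsep)),
              x$pi_low, x$pi_high, x$state))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Upper boundary caps for vapor pressure and solubility
#'
#' Solubility predictions above the concentration of the pure liquid
#' solute (1/MV mol/L) and vapor pressures above standard atmospheric
#' pressure are not physically meaningful in environmental systems.
#' Predictions exceeding these bounds are set to the cap, assigned
#' uncertainty level 6 (boundary violation) and flagged
#' \code{capped}; the RMSEP estimated for the pre-cap uncertainty
#' level is retained.  Idempotent: applying twice changes nothing.
#'
#' @param pred A \code{\link{property_prediction}} for a VP or
#'   solubility endpoint.
#' @param tp \code{\link{thermal_properties}} carrying \code{MV}
#'   (L/mol); required for solubility caps, ignored for VP.
#' @return The (possibly capped) \code{property_prediction}; the
#'   prediction interval is re-centred on the capped value with its
#'   width preserved.
#' @examples
#' p <- property_prediction("SW_liquid", 2, ul = 1L)
#' apply_caps(p, thermal_properties(MV = 0.1))$value  # 1 = log10(1/0.1)
#' @export
apply_caps <- function(pred, tp = thermal_properties()) {
  stopifnot(inherits(pred, "property_prediction"))
  if (!is_solubility_endpoint(pred$endpoint))
    stop("caps apply only to VP/solubility endpoints; got '",
         pred$endpoint, "'")
  if (pred$endpoint == "VP_liquid") {
    cap <- log10(.pc$P_atm)
  } else {
    MV <- tp[["MV"]]
    if (is.null(MV) || !is.finite(MV))
      stop("solubility cap requires MV (L/mol) in the thermal properties")
    if (MV <= 0) stop("MV must be > 0")
    cap <- log10(1 / MV)
  }
  if (!is.finite(pred$value) || pred$value <= cap) return(pred)
  half <- if (is.finite(pred$pi_high)) pred$pi_high - pred$value else NA_real_
  pred$value <- cap
  pred$ul <- 6L
  pred$flags <- unique(c(pred$flags, "capped"))
  if (is.finite(half)) {
    pred$pi_low <- cap - half
    pred$pi_high <- cap + half
  }
  pred
}
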