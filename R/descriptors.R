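#' Abraham solute descriptors
#'
#' Bundle the five Abraham solute descriptors used by the PPLFER
#' equations: \code{S} (dipolarity/polarizability), \code{A} (hydrogen
#' bond donor capacity), \code{B} (hydrogen bond acceptor capacity),
#' \code{V} (McGowan volume, conventional units of cm^3/mol divided by
#' 100) and \code{L} (log hexadecane-air partition coefficient).
#'
#' @param S,A,B,V,L Numeric scalars. \code{A} and \code{B} must be
#'   non-negative, \code{V} strictly positive, all finite.
#' @return An object of class \code{solute_descriptors} (named list).
#' @examples
#' solute_descriptors(S = 0.6, A = 0, B = 0.14, V = 0.7164, L = 2.8)
#' @export
solute_descriptors <- function(S, A, B, V, L) {
  sd <- list(S = S, A = A, B = B, V = V, L = L)
  validate_descriptors(sd)
  structure(sd, class = "solute_descriptors")
}

#' Validate solute descriptors
#'
#' Checks the invariants of the descriptor set (finiteness, \code{A},
#' \code{B} non-negative, \code{V} positive) and errors naming the
#' offending field.  Accepts a \code{solute_descriptors} object, a named
#' list, or a data frame with columns \code{S, A, B, V, L} (each row
#' checked).
#'
#' @param sd Descriptors to validate.
#' @return \code{sd}, invisibly, if valid.
#' @export
validate_descriptors <- function(sd) {
  for (f in c("S", "A", "B", "V", "L")) {
    val <- sd[[f]]
    if (is.null(val) || length(val) == 0L)
      stop("descriptor '", f, "' is missing", call. = FALSE)
    if (!is.numeric(val) || any(!is.finite(val)))
      stop("descriptor '", f, "' is not finite numeric", call. = FALSE)
  }
  if (any(sd[["A"]] < 0)) stop("descriptor 'A' must be >= 0", call. = FALSE)
  if (any(sd[["B"]] < 0)) stop("descriptor 'B' must be >= 0", call. = FALSE)
  if (any(sd[["V"]] <= 0)) stop("descriptor 'V' must be > 0", call. = FALSE)
  invisible(sd)
}

#' @export
print.solute_descriptors <- function(x, ...) {
  cat("Abraham solute descriptors\n")
  print(unlist(x[c("S", "A", "B", "V", "L")]))
  invisible(x)
}

#' Thermal properties of a solute
#'
#' Melting point, boiling point, entropy of fusion and liquid molar
#' volume, used for physical-state classification, the Van't Hoff
#' solid correction and solubility capping.  All fields are optional
#' (\code{NA} when unknown).
#'
#' @param T_M Melting point (K).
#' @param T_B Boiling point (K).
#' @param dS_M Entropy of fusion (J/(mol K)).
#' @param MV Liquid (or supercooled liquid) molar volume (L/mol).
#' @return An object of class \code{thermal_properties}.
#' @examples
#' thermal_properties(T_M = 353.4, T_B = 491.1, dS_M = 54.4, MV = 0.125)
#' @export
thermal_properties <- function(T_M = NA_real_, T_B = NA_real_,
                               dS_M = NA_real_, MV = NA_real_) {
  tp <- list(T_M = as.numeric(T_M), T_B = as.numeric(T_B),
             dS_M = as.numeric(dS_M), MV = as.numeric(MV))
  if (!is.na(tp$T_M) && !is.na(tp$T_B) && tp$T_M >= tp$T_B)
    stop("T_M must be below T_B when both are given", call. = FALSE)
  if (!is.na(tp$MV) && tp$MV <= 0) stop("MV must be > 0", call. = FALSE)
  if (!is.na(tp$dS_M) && tp$dS_M <= 0) stop("dS_M must be > 0", call. = FALSE)
  structure(tp, class = "thermal_properties")
}

#' Fallback molar volume from the McGowan volume
#'
#' Scales the McGowan characteristic volume \code{V} (conventional
#' units, cm^3/mol divided by 100) to an approximate liquid molar
#' volume.  Real molar volumes of organic liquids are typically about
#' 1.27 times the McGowan characteristic volume, i.e. about
#' \code{0.127 * V} L/mol in the conventional descriptor units.
#' Predictions using this fallback are always flagged.
#'
#' @param V McGowan volume descriptor.
#' @return Molar volume in L/mol.
#' @examples
#' mv_from_mcgowan(1)  # about 0.127 L/mol (127 cm^3/mol)
#' @export
mv_from_mcgowan <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be finite and > 0")
  0.127 * V
}
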