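# Thermodynamic property cycles over PPLFER system parameters.
#
# The three-solubility approach interprets K_OW, K_OA and K_AW as
# ratios of solubilities in octanol, water and air, so system
# parameters for one endpoint can be derived coefficient-wise from two
# others, e.g. dry K_OW = K_OA + K_AW, S_O = S_W + K_OW.  Standard
# errors propagate in quadrature (independence assumed) for both sums
# and differences.

.combine_params <- function(sp1, sp2, endpoint, sign) {
  stopifnot(inherits(sp1, "system_parameters"),
            inherits(sp2, "system_parameters"))
  .check_endpoint(endpoint)
  target_units <- .endpoint_units(endpoint)
  # unit algebra: adding a dimensionless log-ratio preserves units;
  # anything else must land on the endpoint's canonical units
  ratio <- "log10(dimensionless ratio)"
  combined_units <-
    if (sp2$units == ratio) sp1$units
    else if (sp1$units == ratio && sign > 0) sp2$units
    else if (sp1$units == sp2$units && sign < 0) ratio
    else NA_character_
  if (is.na(combined_units) || combined_units != target_units)
    stop("endpoint mismatch: combining '", sp1$endpoint, "' [", sp1$units,
         "] and '", sp2$endpoint, "' [", sp2$units,
         "] does not yield units of '", endpoint, "' [", target_units, "]",
         call. = FALSE)
  system_parameters(
    endpoint,
    coef = sp1$coef + sign * sp2$coef,
    se = sqrt(sp1$se^2 + sp2$se^2),
    total_se = sqrt(sp1$total_se^2 + sp2$total_se^2),
    derived = list(op = if (sign > 0) "sum" else "difference",
                   of = c(sp1$endpoint, sp2$endpoint)))
}

#' Derive system parameters as the sum of two endpoints
#'
#' Coefficient-wise sum with quadrature propagation of the
#' per-coefficient and total standard errors, computed on unrounded
#' inputs.  This is how the dry octanol-water row is obtained from the
#' octanol-air and air-water rows, and how the octanol solubilities are
#' obtained from the water solubility and an octanol-water row.
#'
#' @param sp1,sp2 \code{\link{system_parameters}} to combine.
#' @param endpoint Endpoint code of the derived row; its canonical
#'   units must match the unit algebra of the combination, otherwise an
#'   endpoint-mismatch error is raised.
#' @return A derived \code{\link{system_parameters}} object.
#' @examples
#' dry <- derive_sum(builtin_system_parameters("KOA"),
#'                   builtin_system_parameters("KAW"), "KOW_dry")
#' round(dry$coef, 2)  # matches the bundled dry KOW row
#' @export
derive_sum <- function(sp1, sp2, endpoint) {
  .combine_params(sp1, sp2, endpoint, sign = +1)
}

#' Derive system parameters as the difference of two endpoints
#'
#' Coefficient-wise difference; standard errors still add in
#' quadrature (errors of independent quantities accumulate for
#' differences exactly as for sums).  This is how the hypothetical
#' wet/dry octanol partition row (KOO) is obtained from the wet and dry
#' octanol-water rows.
#'
#' @inheritParams derive_sum
#' @return A derived \code{\link{system_parameters}} object.
#' @examples
#' koo <- derive_difference(builtin_system_parameters("KOW_wet"),
#'                          builtin_system_parameters("KOW_dry"), "KOO")
#' round(koo$coef, 2)
#' @export
derive_difference <- function(sp1, sp2, endpoint) {
  .combine_params(sp1, sp2, endpoint, sign = -1)
}

#' Audit the cycle identities of a system-parameter registry
#'
#' Recomputes every cycle-derived row (dry KOW, KOO, dry and wet SO)
#' from the calibrated rows at full floating-point precision and
#' reports the absolute residual against the stored (printed,
#' 2-decimal) coefficients.  A consistent registry has every residual
#' at or below half the last printed digit (0.005).
#'
#' @param registry Named list of \code{system_parameters} covering all
#'   nine endpoints, e.g. \code{\link{pplfer_registry}()}.
#' @param tol Pass threshold for each residual (default 0.005,
#'   i.e. printed 2-decimal rounding).
#' @return Data frame with columns \code{endpoint}, \code{term}
#'   (coefficient name or \code{"total_se"}), \code{stored},
#'   \code{recomputed}, \code{residual}, \code{pass}; attribute
#'   \code{"pass"} gives the overall verdict.
#' @examples
#' aud <- check_cycle_consistency(pplfer_registry())
#' attr(aud, "pass")  # TRUE
#' @export
check_cycle_consistency <- function(registry, tol = 0.005) {
  missing <- setdiff(pplfer_endpoints(), names(registry))
  if (length(missing))
    stop("registry is missing endpoints: ", paste(missing, collapse = ", "))

  # recompute from calibrated rows only, chaining at full precision
  derived <- list()
  derived$KOW_dry <- derive_sum(registry$KOA, registry$KAW, "KOW_dry")
  derived$KOO <- derive_difference(registry$KOW_wet, derived$KOW_dry, "KOO")
  derived$SO_dry_liquid <-
    derive_sum(registry$SW_liquid, derived$KOW_dry, "SO_dry_liquid")
  derived$SO_wet_liquid <-
    derive_sum(registry$SW_liquid, registry$KOW_wet, "SO_wet_liquid")

  rows <- lapply(names(derived), function(ep) {
    stored <- registry[[ep]]
    recomp <- derived[[ep]]
    terms <- c(names(stored$coef), "total_se")
    stored_v <- c(stored$coef, total_se = stored$total_se)
    recomp_v <- c(recomp$coef, total_se = recomp$total_se)
    data.frame(endpoint = ep, term = terms,
               stored = as.numeric(stored_v),
               recomputed = as.numeric(recomp_v),
               residual = abs(as.numeric(stored_v) -
                              round2(as.numeric(recomp_v))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- out$residual <= tol
  attr(out, "pass") <- all(out$pass)
  out
}

#' Round half-even to a fixed number of decimals
#'
#' Thin wrapper over base \code{round}, which already implements the
#' IEC 60559 round-half-to-even rule used when comparing recomputed
#' cycle rows against printed 2-decimal values.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round2 <- function(x, digits = 2) round(x, digits)

#' Calibrate PPLFER system parameters by multiple linear regression
#'
#' Ordinary least squares fit of an observed log property against the
#' Abraham solute descriptors, in either the partition form (S, A, B,
#' V, L and intercept) or the solubility form (adding the
#' \code{sqrt(A*B)} term).  Per-coefficient standard errors come from
#' the OLS covariance matrix; the total standard error is the residual
#' standard deviation.
#'
#' @param data Data frame with descriptor columns \code{S, A, B, V, L}
#'   and the observed property in column \code{y} (or the column named
#'   by \code{y_col}).
#' @param endpoint Endpoint code to stamp on the result.
#' @param form \code{"eq1"} (partition form) or \code{"eq3"}
#'   (solubility form with the \code{d} term).  Defaults to the form
#'   canonical for \code{endpoint}.
#' @param y_col Name of the response column.
#' @return A \code{\link{system_parameters}} object; the fitted
#'   \code{lm} is attached as attribute \code{"fit"}.
#' @examples
#' set.seed(1)
#' dat <- generate_property_dataset(builtin_system_parameters("KAW"),
#'                                  n = 60, noise_sd = 0, seed = 1)
#' calibrate_system_parameters(dat, "KAW")
#' @export
calibrate_system_parameters <- function(data, endpoint,
                                        form = NULL, y_col = "y") {
  .check_endpoint(endpoint)
  if (is.null(form))
    form <- if (is_solubility_endpoint(endpoint)) "eq3" else "eq1"
  form <- match.arg(form, c("eq1", "eq3"))
  need <- c("S", "A", "B", "V", "L", y_col)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("calibration table is missing columns: ",
         paste(miss, collapse = ", "))
  if (any(data$A < 0) || any(data$B < 0))
    stop("A and B must be >= 0 for calibration")

  X <- cbind(S = data$S, A = data$A, B = data$B,
             V = data$V, L = data$L)
  if (form == "eq3") X <- cbind(X, d = sqrt(data$A * data$B))
  p <- ncol(X) + 1L
  if (nrow(X) <= p)
    stop("too few rows (", nrow(X), ") to fit ", p, " coefficients")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p) {
    bad <- colnames(cbind(intercept = 1, X))[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  df <- as.data.frame(X)
  df$.y <- data[[y_col]]
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)
  est <- stats::coef(fit)
  ses <- sm$coefficients[, "Std. Error"]
  pick <- function(v, nm, default = 0) {
    if (nm %in% names(v)) unname(v[[nm]]) else default
  }
  out <- system_parameters(
    endpoint,
    coef = c(s = pick(est, "S"), a = pick(est, "A"), b = pick(est, "B"),
             d = pick(est, "d"), v = pick(est, "V"), l = pick(est, "L"),
             c = pick(est, "(Intercept)")),
    se = c(s = pick(ses, "S"), a = pick(ses, "A"), b = pick(ses, "B"),
           d = pick(ses, "d"), v = pick(ses, "V"), l = pick(ses, "L"),
           c = pick(ses, "(Intercept)")),
    total_se = sm$sigma)
  attr(out, "fit") <- fit
  out
}
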