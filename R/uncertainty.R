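# Applicability-domain diagnostics and prediction uncertainty.
#
# Three complementary AD checks: leverage (extrapolation from the
# training design), chemical similarity score (nearest-neighbour
# similarity, less sensitive to extrapolation) and a negative-domain
# check on atom/bond substructures unseen in training.  The checks are
# combined into an ordinal uncertainty level (UL):
#   UL 0  in AD, no warnings
#   UL 1  in AD, borderline leverage/CSS warning
#   UL 2  out of AD, leverage/CSS warning
#   UL 3  out of AD, egregious extrapolation by leverage
#   UL 4  prediction is intercept-only (all fragment counts zero)
#   UL 5  uncalibrated atom/bond types (negative domain)
#   UL 6  boundary-cap violation; assigned downstream by apply_caps()

#' Applicability-domain context
#'
#' Bundles the training design matrix, the leverage and similarity
#' cut-offs and the set of substructure codes seen in training.  The
#' leverage cut-offs default to multiples of the mean training
#' leverage p/n (1.5, 3 and 10 times for warn / out / egregious); the
#' similarity cut-offs default to 0.5 (warn) and 0.25 (out).  All are
#' configuration, not fitted quantities.
#'
#' @param training_design Numeric matrix, one training chemical per
#'   row (fragment counts or descriptors).
#' @param leverage_warn,leverage_out,leverage_egregious Leverage
#'   thresholds, ordered warn <= out <= egregious.
#' @param css_warn,css_out Similarity thresholds, out <= warn.
#' @param known_substructures Character vector of atom/bond type codes
#'   present in the training data.
#' @return Object of class \code{ad_context}.
#' @export
ad_context <- function(training_design,
                       leverage_warn = NULL, leverage_out = NULL,
                       leverage_egregious = NULL,
                       css_warn = 0.5, css_out = 0.25,
                       known_substructures = character()) {
  X <- as.matrix(training_design)
  if (!nrow(X)) stop("training design is empty")
  ratio <- ncol(X) / nrow(X)
  if (is.null(leverage_warn)) leverage_warn <- 1.5 * ratio
  if (is.null(leverage_out)) leverage_out <- 3 * ratio
  if (is.null(leverage_egregious)) leverage_egregious <- 10 * ratio
  if (!(leverage_warn <= leverage_out && leverage_out <= leverage_egregious))
    stop("leverage thresholds must satisfy warn <= out <= egregious")
  if (css_out > css_warn)
    stop("similarity thresholds must satisfy out <= warn")
  structure(list(training_design = X,
                 leverage_warn = leverage_warn,
                 leverage_out = leverage_out,
                 leverage_egregious = leverage_egregious,
                 css_warn = css_warn, css_out = css_out,
                 known_substructures = as.character(known_substructures)),
            class = "ad_context")
}

#' Leverage of a query point with respect to a training design
#'
#' \code{h = x' (X'X)^{-1} x}, the hat-matrix diagonal a query row
#' would have if appended to the design; a measure of extrapolation
#' from the training chemical space.  Training rows have leverage in
#' (0, 1] and their leverages sum to the number of parameters.  A
#' Moore-Penrose pseudo-inverse is used when \code{X'X} is singular.
#'
#' @param x Numeric query vector (same length as \code{ncol(X)}).
#' @param training_design Numeric training matrix \code{X} or an
#'   \code{\link{ad_context}}.
#' @return Leverage (non-negative scalar).
#' @examples
#' X <- cbind(1, c(1, 2, 3))
#' leverage(c(1, 2), X)  # 1/3
#' @export
leverage <- function(x, training_design) {
  if (inherits(training_design, "ad_context"))
    training_design <- training_design$training_design
  X <- as.matrix(training_design)
  x <- as.numeric(x)
  if (length(x) != ncol(X))
    stop("dimension mismatch: query has ", length(x),
         " features, training design has ", ncol(X))
  XtX <- crossprod(X)
  inv <- tryCatch(solve(XtX), error = function(e) MASS::ginv(XtX))
  drop(t(x) %*% inv %*% x)
}

# Tanimoto similarity for non-negative count vectors:
#   T = <x,y> / (<x,x> + <y,y> - <x,y>)
# 1 for identical non-zero vectors, 0 for disjoint support.  Two
# all-zero vectors are defined as identical (similarity 1).
.tanimoto <- function(x, y) {
  xy <- sum(x * y)
  den <- sum(x * x) + sum(y * y) - xy
  if (den == 0) return(if (all(x == 0) && all(y == 0)) 1 else 0)
  xy / den
}

.cosine <- function(x, y) {
  nx <- sqrt(sum(x * x)); ny <- sqrt(sum(y * y))
  if (nx == 0 || ny == 0) return(if (nx == 0 && ny == 0) 1 else 0)
  sum(x * y) / (nx * ny)
}

#' Chemical similarity score of a query against a training set
#'
#' Mean similarity of the \code{k} most similar training rows under a
#' count-vector similarity (Tanimoto by default, cosine selectable).
#' A score of 1 means the query duplicates a training chemical; 0
#' means it shares no non-zero features with any neighbour.
#'
#' @param x Numeric query vector.
#' @param training_design Training matrix or \code{\link{ad_context}}.
#' @param k Number of nearest neighbours (>= 1); capped at the number
#'   of training rows.
#' @param method \code{"tanimoto"} or \code{"cosine"}.
#' @return Similarity score in [0, 1].
#' @examples
#' X <- rbind(c(1, 0, 2), c(0, 1, 0), c(2, 0, 2))
#' css(c(1, 0, 2), X, k = 1)  # 1: exact training duplicate
#' @export
css <- function(x, training_design, k = 5,
                method = c("tanimoto", "cosine")) {
  method <- match.arg(method)
  if (inherits(training_design, "ad_context"))
    training_design <- training_design$training_design
  X <- as.matrix(training_design)
  if (!nrow(X)) stop("training set is empty")
  if (k < 1) stop("k must be >= 1")
  x <- as.numeric(x)
  if (length(x) != ncol(X))
    stop("dimension mismatch: query has ", length(x),
         " features, training design has ", ncol(X))
  fun <- if (method == "tanimoto") .tanimoto else .cosine
  sims <- apply(X, 1, fun, x = x)
  k <- min(k, length(sims))
  mean(sort(sims, decreasing = TRUE)[seq_len(k)])
}

#' Assign an uncertainty level from the AD diagnostics
#'
#' Combines the negative-domain check, the intercept-only check and
#' the leverage/similarity cut-offs into UL 0-5.  Precedence follows
#' the severity of the condition: unseen substructures (UL 5) dominate
#' everything, then intercept-only predictions (UL 4), then egregious
#' leverage (UL 3), out-of-AD warnings (UL 2) and borderline warnings
#' (UL 1).  UL 6 (boundary violation) is never assigned here; it is
#' applied after prediction by \code{\link{apply_caps}}.
#'
#' @param leverage Leverage of the query (see \code{\link{leverage}}).
#' @param css Similarity score of the query (see \code{\link{css}}).
#' @param ctx \code{\link{ad_context}} with the thresholds and known
#'   substructures.
#' @param fragment_counts Numeric vector of the query's fragment
#'   counts; all zero means the prediction is intercept-only.
#' @param substructures Character vector of atom/bond codes present in
#'   the query.
#' @param bounds_violated Accepted for interface completeness;
#'   boundary violations are handled downstream by
#'   \code{\link{apply_caps}} and do not affect the value returned
#'   here.
#' @return Integer UL in 0..5.
#' @examples
#' ctx <- ad_context(cbind(1, diag(3)), known_substructures = c("C", "O"))
#' assign_ul(0.1, 0.9, ctx, fragment_counts = c(1, 0, 0, 1),
#'           substructures = "C")  # 0
#' @export
assign_ul <- function(leverage, css, ctx, fragment_counts,
                      substructures = character(),
                      bounds_violated = FALSE) {
  stopifnot(inherits(ctx, "ad_context"))
  if (length(setdiff(substructures, ctx$known_substructures)) > 0)
    return(5L)
  if (length(fragment_counts) && all(fragment_counts == 0))
    return(4L)
  if (is.finite(leverage) && leverage > ctx$leverage_egregious)
    return(3L)
  if ((is.finite(leverage) && leverage > ctx$leverage_out) ||
      (is.finite(css) && css < ctx$css_out))
    return(2L)
  if ((is.finite(leverage) && leverage > ctx$leverage_warn) ||
      (is.finite(css) && css < ctx$css_warn))
    return(1L)
  0L
}

#' Aggregate uncertainty across the inputs of a meta-model
#'
#' PPLFER property models are meta-models: their inputs (predicted
#' solute descriptors, calibrated system parameters) each carry their
#' own UL and error estimate.  The aggregate RMSEP follows propagation
#' of uncertainty: the square root of the sum of squared component
#' RMSEPs plus any additional squared standard errors.  The aggregate
#' UL is the maximum component UL; UL 4 components (intercept-only)
#' can be remapped via \code{ul4_as} for endpoints where the intercept
#' is a meaningful in-domain prediction.
#'
#' @param uls Integer vector of component ULs (non-empty).
#' @param rmseps Numeric vector of component RMSEPs (log units).
#' @param extra_se Additional independent standard errors to fold in
#'   (e.g. the total s.e. of the system parameters).
#' @param ul4_as Value UL 4 components count as when taking the
#'   maximum (default 4, i.e. kept as-is).
#' @return List with elements \code{ul} and \code{rmsep}.
#' @examples
#' aggregate_meta(c(0L, 1L), c(0.17, 0.16))$rmsep  # 0.2335 -> 0.23
#' @export
aggregate_meta <- function(uls, rmseps, extra_se = numeric(),
                           ul4_as = 4L) {
  if (!length(uls) || !length(rmseps))
    stop("uls and rmseps must be non-empty")
  if (any(!uls %in% 0:6)) stop("ULs must be integers in 0..6")
  if (any(rmseps < 0) || (length(extra_se) && any(extra_se < 0)))
    stop("RMSEPs and standard errors must be >= 0")
  eff <- ifelse(uls == 4L, ul4_as, uls)
  list(ul = as.integer(max(eff)),
       rmsep = sqrt(sum(rmseps^2) + sum(extra_se^2)))
}

#' Default prediction-interval adjustment factors
#'
#' Empirically calibrated multiplicative widenings of the estimated
#' RMSEP: 1.25 globally for all models; a further 1.67 for vapor
#' pressure and 1.25 for water solubility when the solute is
#' classified (maybe) solid; and a further 1.25 for vapor pressure at
#' UL 2, 3 or 5.  All factors are configuration and can be disabled by
#' setting them to 1.
#'
#' @param global Factor applied to every prediction.
#' @param vp_solid Extra factor for VP of (maybe) solids.
#' @param sw_solid Extra factor for SW of (maybe) solids.
#' @param vp_high_ul Extra factor for VP at UL 2, 3 or 5.
#' @return Named list of factors.
#' @export
pi_adjustments <- function(global = 1.25, vp_solid = 1.67,
                           sw_solid = 1.25, vp_high_ul = 1.25) {
  f <- list(global = global, vp_solid = vp_solid,
            sw_solid = sw_solid, vp_high_ul = vp_high_ul)
  if (any(unlist(f) < 1)) stop("adjustment factors must be >= 1")
  f
}

#' 95\% prediction interval with RMSEP adjustments
#'
#' The interval is \code{M +/- 1.96 * RMSEP_adj}, where the adjusted
#' RMSEP is the estimate multiplied by the applicable factors from
#' \code{\link{pi_adjustments}}.  Adjustments only ever widen the
#' interval.
#'
#' @param M Predicted value (log10 units).
#' @param rmsep Estimated RMSEP (log units), >= 0.
#' @param endpoint Endpoint code (used to select endpoint-specific
#'   factors); \code{NULL} applies only the global factor.
#' @param ul Uncertainty level of the prediction (for the VP high-UL
#'   factor); \code{NA} means not applicable.
#' @param state Predicted physical state (for the solid factors).
#' @param factors Adjustment factors, see \code{\link{pi_adjustments}}.
#' @return List with \code{pi_low}, \code{pi_high} and
#'   \code{rmsep_adj}.
#' @examples
#' prediction_interval(0, 1, "KOW_wet")$pi_high  # 1.96 * 1.25 = 2.45
#' @export
prediction_interval <- function(M, rmsep, endpoint = NULL,
                                ul = NA_integer_, state = "unknown",
                                factors = pi_adjustments()) {
  if (!is.finite(rmsep) || rmsep < 0) stop("rmsep must be >= 0")
  adj <- rmsep * factors$global
  solidish <- state %in% c("solid", "maybe_solid")
  if (!is.null(endpoint)) {
    if (endpoint == "VP_liquid" && solidish) adj <- adj * factors$vp_solid
    if (endpoint == "SW_liquid" && solidish) adj <- adj * factors$sw_solid
    if (endpoint == "VP_liquid" && !is.na(ul) && ul %in% c(2L, 3L, 5L))
      adj <- adj * factors$vp_high_ul
  }
  list(pi_low = M - .pc$z95 * adj, pi_high = M + .pc$z95 * adj,
       rmsep_adj = adj)
}
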