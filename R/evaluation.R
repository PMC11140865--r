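# Validation statistics: RMSEP, UL/state-stratified tables with
# prediction-interval coverage, coverage-driven adjustment-factor
# calibration, and the strong acid/base filter.

#' Root mean squared error of prediction
#'
#' \code{RMSEP = sqrt(sum((y - yhat)^2) / n)} over an external
#' validation set (divide-by-n, not n - p).
#'
#' @param y_exp Experimental log values, or a data frame with columns
#'   \code{y_exp} and \code{y_pred}.
#' @param y_pred Predicted log values (ignored when \code{y_exp} is a
#'   data frame).
#' @return RMSEP in log units.
#' @examples
#' rmsep(c(1, -1), c(0, 0))  # 1
#' @export
rmsep <- function(y_exp, y_pred = NULL) {
  if (is.data.frame(y_exp)) {
    y_pred <- y_exp$y_pred
    y_exp <- y_exp$y_exp
  }
  if (!length(y_exp)) stop("no records: RMSEP of an empty set is undefined")
  if (length(y_exp) != length(y_pred))
    stop("y_exp and y_pred must have equal length")
  if (any(!is.finite(y_exp)) || any(!is.finite(y_pred)))
    stop("y values must be finite")
  sqrt(mean((y_exp - y_pred)^2))
}

# closed-interval PI membership at a given estimated rmsep and factor
.within_pi <- function(resid, rmsep_est, factor = 1) {
  abs(resid) <= .pc$z95 * rmsep_est * factor
}

#' UL/state-stratified validation statistics
#'
#' For each stratum of the records (by uncertainty level, predicted
#' state, dataset membership, or any combination) computes the
#' empirical RMSEP, the percentage of records whose experimental value
#' lies inside the 95\% prediction interval built from the stratum's
#' estimated RMSEP (closed intervals: the boundary counts as inside),
#' and the record count.  Records at UL 6 (boundary-capped) use the
#' RMSEP estimated for their pre-cap UL, supplied either through an
#' \code{ul_precap} column or directly via \code{rmsep_est}.
#'
#' @param records Data frame with columns \code{y_exp}, \code{y_pred},
#'   the grouping columns, and optionally \code{rmsep_est} (per-record
#'   estimated RMSEP) and \code{ul_precap}.
#' @param rmsep_est Estimated RMSEP used for the coverage check: a
#'   single number, a named vector keyed by UL (\code{"0".."6"}), or
#'   \code{NULL} to use the \code{rmsep_est} column.
#' @param by Character vector of grouping columns (default
#'   \code{"ul"}); any subset of the record columns.
#' @param factor Multiplicative adjustment already applied to the
#'   estimated RMSEP (default 1).
#' @return Data frame with the grouping columns plus \code{rmsep},
#'   \code{pct_in}, \code{n}.
#' @export
stratified_stats <- function(records, rmsep_est = NULL, by = "ul",
                             factor = 1) {
  if (!nrow(records)) stop("no records")
  miss <- setdiff(c("y_exp", "y_pred", by), names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  if ("ul" %in% names(records)) {
    if (any(!records$ul %in% 0:6))
      stop("unknown UL value(s): ",
           paste(unique(records$ul[!records$ul %in% 0:6]), collapse = ", "))
  }

  est <- .resolve_rmsep_est(records, rmsep_est)
  resid <- records$y_exp - records$y_pred
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    i <- key == lv
    g <- records[i, by, drop = FALSE][1, , drop = FALSE]
    g$rmsep <- rmsep(records$y_exp[i], records$y_pred[i])
    g$pct_in <- 100 * mean(.within_pi(resid[i], est[i], factor))
    g$n <- sum(i)
    g
  }))
  rownames(out) <- NULL
  out
}

.resolve_rmsep_est <- function(records, rmsep_est) {
  n <- nrow(records)
  if (is.null(rmsep_est)) {
    if (!"rmsep_est" %in% names(records))
      stop("provide rmsep_est or an rmsep_est column")
    est <- records$rmsep_est
  } else if (length(rmsep_est) == 1L && is.null(names(rmsep_est))) {
    est <- rep(as.numeric(rmsep_est), n)
  } else {
    if (!"ul" %in% names(records))
      stop("a UL-keyed rmsep_est needs a 'ul' column")
    # UL 6 records fall back to the pre-cap UL's estimate
    ul_key <- records$ul
    if ("ul_precap" %in% names(records))
      ul_key <- ifelse(ul_key == 6 & !is.na(records$ul_precap),
                       records$ul_precap, ul_key)
    est <- as.numeric(rmsep_est[as.character(ul_key)])
    if (any(is.na(est)))
      stop("no RMSEP estimate for UL(s): ",
           paste(unique(ul_key[is.na(est)]), collapse = ", "))
  }
  if (any(!is.finite(est)) || any(est < 0))
    stop("estimated RMSEPs must be finite and >= 0")
  est
}

#' Calibrate PI adjustment factors from observed coverage
#'
#' For each stratum, walks the geometric ladder 1, step, step^2, ...
#' and returns the smallest factor at which the 95\% prediction
#' intervals (closed) built from \code{factor * rmsep_est} contain at
#' least the target fraction of the experimental values.
#' Deterministic given the records.
#'
#' @inheritParams stratified_stats
#' @param target Required coverage fraction, in (0, 1); default 0.95.
#' @param step Ladder ratio, > 1; default 1.25.
#' @param max_steps Safety bound on the ladder length.
#' @return Data frame with the grouping columns plus \code{factor},
#'   \code{coverage} (achieved, as a fraction) and \code{n}.
#' @examples
#' rec <- data.frame(y_exp = qnorm((1:200 - 0.5) / 200), y_pred = 0,
#'                   ul = 0L, rmsep_est = 1)
#' calibrate_adjustments(rec)$factor  # 1: already covered
#' @export
calibrate_adjustments <- function(records, rmsep_est = NULL, by = "ul",
                                  target = 0.95, step = 1.25,
                                  max_steps = 60L) {
  if (!nrow(records)) stop("no records")
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("target must be in (0, 1)")
  if (!is.finite(step) || step <= 1) stop("step must be > 1")
  miss <- setdiff(c("y_exp", "y_pred", by), names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))

  est <- .resolve_rmsep_est(records, rmsep_est)
  resid <- records$y_exp - records$y_pred
  if (any(!is.finite(resid)))
    stop("non-finite residuals: coverage cannot be attained")
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    i <- key == lv
    g <- records[i, by, drop = FALSE][1, , drop = FALSE]
    fac <- 1
    k <- 0L
    repeat {
      cov <- mean(.within_pi(resid[i], est[i], fac))
      if (cov >= target) break
      k <- k + 1L
      if (k > max_steps)
        stop("coverage target ", target, " not attainable for stratum '",
             lv, "' within ", max_steps, " ladder steps")
      fac <- step^k
    }
    g$factor <- fac
    g$coverage <- cov
    g$n <- sum(i)
    g
  }))
  rownames(out) <- NULL
  out
}

#' Remove strong acids and bases from an evaluation dataset
#'
#' Measurements for ionizable chemicals can reflect distribution
#' ratios of the ion mixture rather than the neutral-species property.
#' Records are removed when an acid pKa is strictly below 4 or a base
#' pKa is strictly above 10; records without pKa data are kept.
#'
#' @param records Data frame; optional columns \code{pKa_acid} and
#'   \code{pKa_base} (NA when unknown).
#' @param acid_below Acid pKa cut-off (strict), default 4.
#' @param base_above Base pKa cut-off (strict), default 10.
#' @return List with \code{kept} and \code{removed} data frames; the
#'   removed records carry a \code{reason} column.
#' @examples
#' rec <- data.frame(id = c("a", "b", "c"),
#'                   pKa_acid = c(3.5, NA, 4.0),
#'                   pKa_base = c(NA, 10.5, NA))
#' filter_ionizable(rec)$removed$id  # "a", "b"
#' @export
filter_ionizable <- function(records, acid_below = 4, base_above = 10) {
  n <- nrow(records)
  pa <- if ("pKa_acid" %in% names(records)) records$pKa_acid else
    rep(NA_real_, n)
  pb <- if ("pKa_base" %in% names(records)) records$pKa_base else
    rep(NA_real_, n)
  strong_acid <- !is.na(pa) & pa < acid_below
  strong_base <- !is.na(pb) & pb > base_above
  drop <- strong_acid | strong_base
  removed <- records[drop, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- ifelse(strong_acid[drop] & strong_base[drop],
                             "strong acid and base",
                             ifelse(strong_acid[drop], "strong acid",
                                    "strong base"))
  } else {
    removed$reason <- character(0)
  }
  list(kept = records[!drop, , drop = FALSE], removed = removed)
}
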