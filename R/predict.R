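# Batch prediction over a solute table: all nine endpoints per solute
# with state classification, optional solid conversion, boundary caps,
# AD-based uncertainty levels, RMSEP aggregation and prediction
# intervals.

#' Prediction configuration
#'
#' Collects the tunable settings of the prediction pipeline.  Values
#' can also be loaded from a YAML file (see \code{\link{read_config}});
#' unspecified keys keep these defaults.
#'
#' @param system_T_K System temperature (K); default 298.15 (25 C).
#' @param state_margin_K Half-width of the \code{maybe_solid} band in
#'   \code{\link{classify_state}}.
#' @param default_dS_M Entropy of fusion (J/(mol K)) assumed when a
#'   solute lacks one (Walden's rule, 56.5); its use is flagged.
#' @param enable_MV_fallback Use \code{\link{mv_from_mcgowan}} when a
#'   molar volume is missing (flagged); when \code{FALSE}, solubility
#'   capping without a molar volume is an error.
#' @param solid_output \code{"supercooled"} (default; report the
#'   supercooled-liquid value for solids, the convention of fate and
#'   transport models) or \code{"solid"} (apply the Van't Hoff
#'   correction for solutes classified solid or maybe_solid).
#' @param pi_factors Prediction-interval adjustment factors, see
#'   \code{\link{pi_adjustments}}.
#' @param ul4_as How UL 4 components count in meta aggregation, see
#'   \code{\link{aggregate_meta}}.
#' @param endpoints Endpoints to predict; default all nine.
#' @return Named list of class \code{pplfer_config}.
#' @export
pplfer_config <- function(system_T_K = 298.15, state_margin_K = 10,
                          default_dS_M = 56.5,
                          enable_MV_fallback = TRUE,
                          solid_output = c("supercooled", "solid"),
                          pi_factors = pi_adjustments(),
                          ul4_as = 4L,
                          endpoints = pplfer_endpoints()) {
  solid_output <- match.arg(solid_output)
  bad <- setdiff(endpoints, pplfer_endpoints())
  if (length(bad)) stop("unknown endpoints: ", paste(bad, collapse = ", "))
  structure(list(system_T_K = system_T_K,
                 state_margin_K = state_margin_K,
                 default_dS_M = default_dS_M,
                 enable_MV_fallback = enable_MV_fallback,
                 solid_output = solid_output,
                 pi_factors = pi_factors,
                 ul4_as = ul4_as,
                 endpoints = endpoints),
            class = "pplfer_config")
}

#' Load a prediction configuration from YAML
#'
#' Reads a YAML mapping and merges it over the defaults of
#' \code{\link{pplfer_config}}; the \code{pi_factors} key may itself
#' be a mapping with the \code{\link{pi_adjustments}} fields.
#'
#' @param path Path to a YAML file.
#' @return A \code{pplfer_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$pi_factors))
    raw$pi_factors <- do.call(pi_adjustments, raw$pi_factors)
  do.call(pplfer_config, raw)
}

.required_cols <- c("id", "S", "A", "B", "V", "L")

#' Read a solute table from CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal.  Required columns: \code{id, S,
#' A, B, V, L}; recognised optional columns: \code{smiles} (carried as
#' opaque text), \code{Tm_K, Tb_K, dSm_J_molK, MV_L_mol, pKa_acid,
#' pKa_base, ul}.  Unknown columns pass through untouched.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_solute_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_solute_table(df)
  df
}

#' Validate a solute input table
#'
#' Checks for the required columns and numeric, finite descriptor
#' cells, naming the offending column or row id in the error.
#'
#' @param df Data frame to check.
#' @return \code{df}, invisibly.
#' @export
validate_solute_table <- function(df) {
  miss <- setdiff(.required_cols, names(df))
  if (length(miss))
    stop("input table is missing required columns: ",
         paste(miss, collapse = ", "))
  for (col in c("S", "A", "B", "V", "L")) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop("column '", col, "' is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-finite value in column '", col, "' for row id(s): ",
           paste(df$id[utils::head(bad, 5)], collapse = ", "))
  }
  invisible(df)
}

.num_or_na <- function(df, col, i) {
  if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]][i]))
  else NA_real_
}

#' Batch property prediction over a solute table
#'
#' For every solute, evaluates the PPLFER equations of every requested
#' endpoint and assembles a full \code{\link{property_prediction}} per
#' (solute, endpoint): physical-state classification, optional
#' Van't Hoff conversion to the solid state, uncertainty-level
#' assignment from a supplied AD context (or pass-through of an
#' \code{ul} input column), RMSEP aggregation, adjusted 95\%
#' prediction intervals, and boundary caps on vapor pressure and
#' solubility.
#'
#' @param input Solute table (see \code{\link{read_solute_table}}), or
#'   a path to a CSV file.
#' @param config A \code{\link{pplfer_config}}.
#' @param registry System parameters to use; default the bundled
#'   registry.
#' @param ad Optional \code{\link{ad_context}} for UL assignment.
#' @param fragments Optional numeric matrix of per-solute fragment
#'   counts (rows aligned with \code{input}), required with \code{ad}.
#' @param substructures Optional list of per-solute character vectors
#'   of substructure codes, used for the negative-domain check.
#' @param descriptor_rmseps Optional named numeric vector of RMSEPs of
#'   upstream descriptor predictions, folded into the aggregate RMSEP
#'   (meta-model propagation).  Empty by default: descriptors are
#'   taken as exact inputs.
#' @return Data frame, one row per (solute, endpoint): \code{id,
#'   endpoint, units, value, ul, rmsep, pi_low, pi_high, state, flags}
#'   (flags semicolon-joined).
#' @examples
#' tab <- generate_solutes(3, seed = 7)
#' head(predict_batch(tab, endpoints = "KOW_wet"))
#' @param endpoints Endpoints to predict, overriding the config.
#' @export
predict_batch <- function(input, config = pplfer_config(),
                          registry = pplfer_registry(), ad = NULL,
                          fragments = NULL, substructures = NULL,
                          descriptor_rmseps = numeric(),
                          endpoints = NULL) {
  if (is.character(input) && length(input) == 1L)
    input <- read_solute_table(input)
  validate_solute_table(input)
  if (is.null(endpoints)) endpoints <- config$endpoints
  if (!is.null(ad) && is.null(fragments))
    stop("an AD context needs per-solute fragment counts")
  if (!is.null(fragments)) {
    fragments <- as.matrix(fragments)
    if (nrow(fragments) != nrow(input))
      stop("fragments must have one row per input solute")
  }

  T_sys <- config$system_T_K
  rows <- vector("list", nrow(input) * length(endpoints))
  r <- 0L
  for (i in seq_len(nrow(input))) {
    sd_i <- list(S = input$S[i], A = input$A[i], B = input$B[i],
                 V = input$V[i], L = input$L[i])
    tp_i <- list(T_M = .num_or_na(input, "Tm_K", i),
                 T_B = .num_or_na(input, "Tb_K", i),
                 dS_M = .num_or_na(input, "dSm_J_molK", i),
                 MV = .num_or_na(input, "MV_L_mol", i))
    state <- classify_state(tp_i, T = T_sys,
                            margin = config$state_margin_K)

    # uncertainty level: computed from the AD context when given,
    # otherwise passed through from the input table
    base_flags <- character()
    if (!is.null(ad)) {
      lev <- leverage(fragments[i, ], ad)
      sim <- css(fragments[i, ], ad)
      subs <- if (is.null(substructures)) character()
              else substructures[[i]]
      ul_i <- assign_ul(lev, sim, ad, fragments[i, ], subs)
      if (ul_i == 4L) base_flags <- c(base_flags, "intercept_only")
      if (ul_i == 5L)
        base_flags <- c(base_flags, "uncalibrated_substructure")
    } else {
      ul_i <- if ("ul" %in% names(input)) as.integer(input$ul[i])
              else NA_integer_
    }

    for (ep in endpoints) {
      sp <- registry[[ep]]
      if (is.null(sp)) stop("registry has no endpoint '", ep, "'")
      flags <- base_flags
      solub <- is_solubility_endpoint(ep)
      value <- .pplfer_value(sp, sd_i)

      if (solub && config$solid_output == "solid" &&
          state %in% c("solid", "maybe_solid") &&
          is.finite(tp_i$T_M) && tp_i$T_M > T_sys) {
        dsm <- tp_i$dS_M
        if (!is.finite(dsm)) {
          dsm <- config$default_dS_M
          flags <- c(flags, "default_dS_M")
        }
        value <- vant_hoff_correct(value, dS_M = dsm, T_M = tp_i$T_M,
                                   T = T_sys)
        flags <- c(flags, "vant_hoff_applied")
      }

      agg <- aggregate_meta(uls = if (is.na(ul_i)) 0L else ul_i,
                            rmseps = sp$total_se,
                            extra_se = descriptor_rmseps,
                            ul4_as = config$ul4_as)
      rm_i <- agg$rmsep
      pi <- prediction_interval(value, rm_i, endpoint = ep, ul = ul_i,
                                state = state,
                                factors = config$pi_factors)
      pred <- property_prediction(ep, value, ul = ul_i, rmsep = rm_i,
                                  pi_low = pi$pi_low,
                                  pi_high = pi$pi_high,
                                  state = state, flags = flags)
      if (solub) {
        tp_cap <- tp_i
        if (!is.finite(tp_cap$MV) && ep != "VP_liquid") {
          if (config$enable_MV_fallback) {
            tp_cap$MV <- mv_from_mcgowan(sd_i$V)
            pred$flags <- unique(c(pred$flags, "mv_fallback"))
          } else {
            stop("solubility cap for '", input$id[i],
                 "' needs MV_L_mol (or enable_MV_fallback)")
          }
        }
        pred <- apply_caps(pred, tp_cap)
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        id = input$id[i], endpoint = ep, units = sp$units,
        value = pred$value, ul = pred$ul, rmsep = pred$rmsep,
        pi_low = pred$pi_low, pi_high = pred$pi_high,
        state = pred$state,
        flags = paste(pred$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a prediction (or any result) table to CSV
#'
#' RFC-4180 CSV, UTF-8, '.' decimal, no row names; the dialect
#' round-trips through \code{\link{read_prediction_table}}.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_prediction_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a prediction table written by
#' \code{\link{write_prediction_table}}
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_prediction_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
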