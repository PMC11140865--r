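# Synthetic fixture generators.  Everything the test-suite consumes is
# generated here from a seed: descriptor populations spanning typical
# neutral organics, noisy property datasets with known true system
# parameters, and sparse fragment-count matrices for the AD machinery.

# run expr under a fixed RNG state without disturbing the caller's
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# inverse-CDF draw from an exponential truncated at `cap`
.rtexp <- function(n, mean, cap) {
  u <- runif(n)
  -mean * log(1 - u * (1 - exp(-cap / mean)))
}

#' Generate a synthetic population of solutes
#'
#' Draws descriptor sets spanning the range of typical neutral organic
#' chemicals: V uniform on (0.3, 4.0) (up to very large solutes),
#' L correlated with V (3.5 V plus Gaussian noise, sd 0.8), S uniform
#' on (0, 2.5), A and B exponential (means 0.25 and 0.45) truncated at
#' 1.5 and 2.5.  Thermal properties are drawn consistently
#' (T_M < T_B always; entropy of fusion around Walden's-rule 56.5
#' J/(mol K); molar volume 0.127 V L/mol with 10\% noise).  The same
#' seed always reproduces the same table.
#'
#' @param n Number of solutes (>= 1).
#' @param seed Integer RNG seed.
#' @return Data frame with columns \code{id, S, A, B, V, L, Tm_K,
#'   Tb_K, dSm_J_molK, MV_L_mol}.
#' @examples
#' head(generate_solutes(5, seed = 42))
#' @export
generate_solutes <- function(n, seed = 1L) {
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  .with_seed(seed, {
    V <- runif(n, 0.3, 4.0)
    L <- 3.5 * V + rnorm(n, 0, 0.8)
    S <- runif(n, 0, 2.5)
    A <- .rtexp(n, 0.25, 1.5)
    B <- .rtexp(n, 0.45, 2.5)
    Tb <- pmax(250, 273 + 100 * V + rnorm(n, 0, 25))
    Tm <- pmax(120, Tb - runif(n, 80, 250))
    dSm <- pmax(20, rnorm(n, 56.5, 8))
    MV <- 0.127 * V * (1 + rnorm(n, 0, 0.1))
    MV <- pmax(MV, 0.01)
    data.frame(id = sprintf("sol%04d", seq_len(n)),
               S = S, A = A, B = B, V = V, L = L,
               Tm_K = Tm, Tb_K = Tb, dSm_J_molK = dSm, MV_L_mol = MV,
               stringsAsFactors = FALSE)
  })
}

#' Generate a noisy property dataset from known system parameters
#'
#' Evaluates the PPLFER equation of \code{params} over a synthetic
#' solute population and adds Gaussian noise, yielding a
#' calibration/evaluation table with both the noise-free truth and the
#' observed value.  With \code{noise_sd = 0},
#' \code{\link{calibrate_system_parameters}} recovers \code{params}
#' exactly.
#'
#' @param params True \code{\link{system_parameters}}.
#' @param n Number of rows.
#' @param noise_sd Gaussian noise standard deviation (log units),
#'   >= 0.
#' @param seed Integer RNG seed.
#' @return Data frame with \code{id, S, A, B, V, L, y_true, y}.
#' @export
generate_property_dataset <- function(params, n, noise_sd = 0.2,
                                      seed = 1L) {
  stopifnot(inherits(params, "system_parameters"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  sol <- generate_solutes(n, seed = seed)
  y_true <- .pplfer_value(params, sol)
  noise <- .with_seed(seed + 1L, rnorm(n, 0, noise_sd))
  out <- sol[c("id", "S", "A", "B", "V", "L")]
  out$y_true <- y_true
  out$y <- y_true + noise
  out
}

#' Generate a fragment-count design with controlled AD violations
#'
#' Builds a sparse non-negative integer training design plus query
#' rows of three kinds: a fraction carrying a substructure code absent
#' from training (forcing UL 5), a fraction with all-zero fragment
#' counts (intercept-only, UL 4), and the remainder drawn from the
#' training distribution.  Category membership of each query is
#' sampled independently with the given probabilities and returned in
#' \code{query_kind}.
#'
#' @param n_train,n_query,n_features Dimensions (>= 1).
#' @param seed Integer RNG seed.
#' @param ul5_fraction,ul4_fraction Probabilities that a query row is
#'   constructed as an unseen-substructure or all-zero case.
#' @return List with \code{training} (matrix), \code{query} (matrix),
#'   \code{known_substructures}, \code{query_substructures} (list of
#'   character vectors per query) and \code{query_kind}
#'   (\code{"ul5"}, \code{"ul4"} or \code{"in_domain"}).
#' @export
generate_fragment_matrix <- function(n_train, n_query, n_features,
                                     seed = 1L, ul5_fraction = 0.1,
                                     ul4_fraction = 0.1) {
  if (min(n_train, n_query, n_features) < 1)
    stop("all dimensions must be >= 1")
  if (ul5_fraction + ul4_fraction > 1)
    stop("ul5_fraction + ul4_fraction must be <= 1")
  .with_seed(seed, {
    feats <- sprintf("f%02d", seq_len(n_features))
    training <- matrix(rpois(n_train * n_features, 0.6),
                       nrow = n_train, dimnames = list(NULL, feats))
    # guarantee every feature is seen in training at least once
    zero_cols <- which(colSums(training) == 0)
    for (j in zero_cols) training[sample.int(n_train, 1L), j] <- 1L
    known <- feats

    kind <- sample(c("ul5", "ul4", "in_domain"), n_query, replace = TRUE,
                   prob = c(ul5_fraction, ul4_fraction,
                            1 - ul5_fraction - ul4_fraction))
    query <- matrix(rpois(n_query * n_features, 0.6),
                    nrow = n_query, dimnames = list(NULL, feats))
    query[kind == "ul4", ] <- 0L
    # in-domain and ul5 rows must not be intercept-only by chance
    fix <- which(kind != "ul4" & rowSums(query) == 0)
    for (i in fix) query[i, sample.int(n_features, 1L)] <- 1L
    subs <- lapply(seq_len(n_query), function(i) {
      s <- feats[query[i, ] > 0]
      if (kind[i] == "ul5") s <- c(s, "x_unseen")
      s
    })
    list(training = training, query = query,
         known_substructures = known,
         query_substructures = subs, query_kind = kind)
  })
}
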